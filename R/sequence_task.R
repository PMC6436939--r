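# Sequence construction, session scheduling and behavioural metrics for the
# cued five-press timing task.

#' Target inter-press intervals (ms)
#'
#' The five trained inter-press intervals of the task. Every sequence's
#' interval order is a permutation of this multiset; the first interval (go to
#' press 1) is shared across the four trained sequences.
#'
#' @export
cq_target_intervals <- c(550, 650, 800, 983, 1300)

#' Construct a single sequence specification
#'
#' A trained sequence couples a finger order (five distinct fingers, labelled
#' 1-5 from thumb to little finger) with an interval order (a permutation of
#' [cq_target_intervals]). The k-th interval is the target time from press
#' k-1 to press k, with the first interval measured from the go cue.
#'
#' @param id Character label, e.g. `"F1T1"`.
#' @param finger_order Integer vector of 5 distinct finger labels in 1..5.
#' @param interval_order Numeric vector of 5 target intervals (ms), a
#'   permutation of [cq_target_intervals].
#' @param finger_order_id,interval_order_id Factor labels (`"F1"`/`"F2"`,
#'   `"T1"`/`"T2"`) recording the factorial cell.
#' @return An object of class `"sequence_spec"`.
#' @export
sequence_spec <- function(id, finger_order, interval_order,
                          finger_order_id = NA_character_,
                          interval_order_id = NA_character_) {
  finger_order <- as.integer(finger_order)
  if (length(finger_order) != 5L || anyDuplicated(finger_order) ||
      !all(finger_order %in% 1:5))
    stop("finger_order must be 5 distinct finger labels in 1..5")
  interval_order <- as.numeric(interval_order)
  if (length(interval_order) != 5L ||
      !identical(sort(interval_order), sort(cq_target_intervals)))
    stop("interval_order must be a permutation of the target intervals ",
         paste(cq_target_intervals, collapse = ", "))
  structure(list(id = as.character(id),
                 finger_order = finger_order,
                 interval_order = as.numeric(interval_order),
                 finger_order_id = finger_order_id,
                 interval_order_id = interval_order_id),
            class = "sequence_spec")
}

#' @export
print.sequence_spec <- function(x, ...) {
  cat(sprintf("<sequence_spec %s> fingers: %s | intervals: %s ms\n", x$id,
              paste(x$finger_order, collapse = "-"),
              paste(x$interval_order, collapse = ", ")))
  invisible(x)
}

#' Build the factorial sequence set
#'
#' Crosses finger orders with interval orders into the full factorial set of
#' trained sequences (F-major order). All finger orders must share their first
#' finger and all interval orders their first interval, mirroring the task
#' constraint that the first press and its target latency are common to every
#' sequence.
#'
#' @param finger_orders List of finger-order vectors (each 5 distinct fingers).
#' @param interval_orders List of interval-order vectors (each a permutation of
#'   [cq_target_intervals]).
#' @return Named list of [sequence_spec()] objects, length
#'   `length(finger_orders) * length(interval_orders)`.
#' @examples
#' s <- build_sequence_set(list(1:5, c(1, 3, 5, 2, 4)),
#'                         list(cq_target_intervals,
#'                              c(550, 983, 1300, 650, 800)))
#' names(s)  # "F1T1" "F1T2" "F2T1" "F2T2"
#' @export
build_sequence_set <- function(finger_orders, interval_orders) {
  if (!length(finger_orders) || !length(interval_orders))
    stop("need at least one finger order and one interval order")
  f1 <- vapply(finger_orders, function(x) x[1], numeric(1))
  i1 <- vapply(interval_orders, function(x) x[1], numeric(1))
  if (length(unique(f1)) != 1L)
    stop("all finger orders must share the same first finger")
  if (length(unique(i1)) != 1L)
    stop("all interval orders must share the same first interval")
  out <- list()
  for (fi in seq_along(finger_orders)) {
    for (ti in seq_along(interval_orders)) {
      id <- sprintf("F%dT%d", fi, ti)
      out[[id]] <- sequence_spec(id, finger_orders[[fi]],
                                 interval_orders[[ti]],
                                 finger_order_id = sprintf("F%d", fi),
                                 interval_order_id = sprintf("T%d", ti))
    }
  }
  out
}

#' Default 2 x 2 sequence set
#'
#' A fixed counterbalanced sequence set: the second finger and interval orders
#' are derangements of the first on positions 2-5 (position 1 is always
#' shared). Derangement keeps the finger, timing and position codes fully
#' dissociable under the transfer analyses.
#'
#' @return Named list of four [sequence_spec()] objects.
#' @export
default_sequences <- function() {
  build_sequence_set(list(1:5, c(1L, 3L, 5L, 2L, 4L)),
                     list(cq_target_intervals,
                          c(550, 983, 1300, 650, 800)))
}

#' Draw a random per-participant sequence set
#'
#' Emulates the task's per-participant randomization: finger and interval
#' orders are drawn at random subject to the shared-first-element constraint,
#' with the second order required to differ from the first at every position
#' 2-5 so the factorial transfer structure stays identifiable.
#'
#' @param seed Integer seed.
#' @return Named list of four [sequence_spec()] objects.
#' @export
random_sequence_set <- function(seed) {
  set.seed(seed)
  derange_rest <- function(first_order) {
    repeat {
      perm <- c(first_order[1], sample(first_order[-1]))
      if (all(perm[2:5] != first_order[2:5])) return(perm)
    }
  }
  f1 <- c(1L, sample(2:5))
  t1 <- c(cq_target_intervals[1], sample(cq_target_intervals[-1]))
  build_sequence_set(list(f1, derange_rest(f1)), list(t1, derange_rest(t1)))
}

#' Schedule a session of trials
#'
#' Builds `n_blocks` blocks, each a seeded random permutation of every
#' sequence id repeated `reps_per_sequence_per_block` times, so per-sequence
#' counts are exactly balanced within each block.
#'
#' @param n_blocks Number of blocks.
#' @param reps_per_sequence_per_block Repetitions of each sequence per block.
#' @param sequences Sequence set as returned by [build_sequence_set()].
#' @param seed Integer seed; the schedule is reproducible given the seed.
#' @return An object of class `"session_schedule"`: list with `blocks` (list of
#'   character vectors of sequence ids) and `seed`.
#' @export
schedule_session <- function(n_blocks, reps_per_sequence_per_block,
                             sequences, seed) {
  if (n_blocks < 1L || reps_per_sequence_per_block < 1L)
    stop("counts must be positive")
  if (!length(sequences)) stop("need at least one sequence")
  ids <- names(sequences)
  if (is.null(ids)) ids <- vapply(sequences, `[[`, "", "id")
  set.seed(seed)
  blocks <- lapply(seq_len(n_blocks), function(b)
    sample(rep(ids, reps_per_sequence_per_block)))
  structure(list(blocks = blocks, seed = as.integer(seed)),
            class = "session_schedule")
}

#' Flatten a schedule to a per-trial table
#' @param schedule A `"session_schedule"`.
#' @return data.frame with columns `trial`, `block`, `sequence_id`.
#' @export
schedule_trials <- function(schedule) {
  ids <- unlist(schedule$blocks, use.names = FALSE)
  data.frame(trial = seq_along(ids),
             block = rep(seq_along(schedule$blocks),
                         lengths(schedule$blocks)),
             sequence_id = ids, stringsAsFactors = FALSE)
}

#' Record one produced trial
#'
#' Press times are on the go-cue clock (go = 0 ms). Produced intervals are the
#' consecutive differences of (go, press 1, ..., press 5), so the first
#' produced "interval" is the go-to-press-1 latency, scored against the first
#' target interval.
#'
#' @param sequence_id Id of the cued sequence.
#' @param press_fingers Integer vector of produced finger labels.
#' @param press_times Numeric vector of press onsets (ms after go).
#' @param spec Optional [sequence_spec()]; if given, `correct_fingers` is
#'   evaluated against it.
#' @param correct_fingers Optional logical override.
#' @return An object of class `"trial_result"`.
#' @export
trial_result <- function(sequence_id, press_fingers, press_times,
                         spec = NULL, correct_fingers = NULL) {
  press_fingers <- as.integer(press_fingers)
  press_times <- as.numeric(press_times)
  complete <- length(press_times) == 5L && !anyNA(press_times)
  if (complete && any(diff(press_times) <= 0))
    stop("press_times must be strictly increasing")
  if (is.null(correct_fingers)) {
    correct_fingers <- if (is.null(spec)) NA else
      complete && identical(press_fingers, spec$finger_order)
  }
  structure(list(sequence_id = sequence_id,
                 press_fingers = press_fingers,
                 press_times = press_times,
                 complete = complete,
                 correct_fingers = correct_fingers,
                 produced_intervals =
                   if (complete) diff(c(0, press_times)) else rep(NA_real_, 5)),
            class = "trial_result")
}

#' Temporal error of a produced trial
#'
#' Mean absolute deviation of the five produced intervals from their targets,
#' expressed as a percentage of the respective target interval. The signed
#' mean (negative = faster than target) supports analyses of temporal
#' compression. Incomplete trials are flagged and return `NA` errors.
#'
#' @param trial A [trial_result()].
#' @param spec The cued [sequence_spec()].
#' @return List with `abs_pct`, `signed_pct` and `complete`.
#' @export
temporal_error <- function(trial, spec) {
  if (!isTRUE(trial$complete))
    return(list(abs_pct = NA_real_, signed_pct = NA_real_, complete = FALSE))
  rel <- (trial$produced_intervals - spec$interval_order) / spec$interval_order
  list(abs_pct = mean(abs(rel)) * 100,
       signed_pct = mean(rel) * 100,
       complete = TRUE)
}

#' Points awarded for one trial
#'
#' Two points for a correct finger sequence with temporal error strictly below
#' 30%, one point for a correct finger sequence below 60%, zero otherwise.
#'
#' @inheritParams temporal_error
#' @return Integer 0, 1 or 2.
#' @export
score_trial <- function(trial, spec) {
  correct <- isTRUE(trial$complete) &&
    identical(trial$press_fingers, spec$finger_order)
  if (!correct) return(0L)
  err <- temporal_error(trial, spec)$abs_pct
  if (err < 30) 2L else if (err < 60) 1L else 0L
}

#' Mean absolute reaction-time deviation in the synchronization test
#'
#' @param responses Press onsets (ms), paired by position with `cue_onsets`.
#' @param cue_onsets Target onsets (ms).
#' @return Mean of `|response - cue|` in ms.
#' @export
sync_rt_deviation <- function(responses, cue_onsets) {
  if (length(responses) != length(cue_onsets))
    stop("responses and cue_onsets must have equal length")
  mean(abs(responses - cue_onsets))
}

#' Median split of a per-participant error metric
#'
#' Splits values into a low ("more accurate") and a high group at the median.
#' Ties at the median go to the low-error group.
#'
#' @param values Numeric vector (e.g. per-participant error rates), length >= 2.
#' @return List with integer index vectors `low` and `high`.
#' @export
median_split <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  m <- stats::median(values)
  list(low = which(values <= m), high = which(values > m))
}

#' Pearson correlation with a t-distribution p value
#'
#' @param x,y Numeric vectors of equal length >= 3 with finite values.
#' @param tail `"two"` for a two-sided p value, `"one"` for a one-sided p value
#'   in the hypothesised `direction`.
#' @param direction For `tail = "one"`: `"negative"` or `"positive"` states the
#'   directional hypothesis; `"auto"` (default) takes the observed sign.
#' @return List with `r`, `t`, `df` and `p`.
#' @export
correlate <- function(x, y, tail = c("two", "one"),
                      direction = c("auto", "negative", "positive")) {
  tail <- match.arg(tail)
  direction <- match.arg(direction)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for zero-variance input")
  r <- stats::cor(x, y)
  df <- length(x) - 2L
  tt <- r * sqrt(df / (1 - r^2))
  p <- if (tail == "two") {
    2 * stats::pt(-abs(tt), df)
  } else {
    sgn <- switch(direction, auto = sign(tt), negative = -1, positive = 1)
    if (sgn >= 0) stats::pt(tt, df, lower.tail = FALSE) else stats::pt(tt, df)
  }
  list(r = r, t = tt, df = df, p = p)
}
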