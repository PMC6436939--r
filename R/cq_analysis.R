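# Competitive-queuing statistics and confound controls: preparation-window
# probabilities, the CQ distance across transfer regimes, slope and
# pattern-similarity controls, production peaks, and behaviour links.

#' Enumerate train/test sequence pairs for a transfer regime
#'
#' Transfer regimes factor the decoded code: `within` trains and tests on the
#' same sequence; `temporal` keeps the interval order but changes the finger
#' order; `spatial` keeps the finger order but changes the interval order;
#' `positional` changes both, leaving only ordinal position shared.
#'
#' @param sequences The complete 2 x 2 factorial sequence set.
#' @param mode One of `"within"`, `"temporal"`, `"spatial"`, `"positional"`.
#' @return data.frame with columns `train` and `test` (sequence ids); each
#'   mode yields 4 ordered pairs.
#' @export
pair_transfer <- function(sequences, mode = c("within", "temporal",
                                              "spatial", "positional")) {
  mode <- match.arg(mode)
  ids <- names(sequences)
  fid <- vapply(sequences, `[[`, "", "finger_order_id")
  tid <- vapply(sequences, `[[`, "", "interval_order_id")
  if (length(ids) != 4L || length(unique(fid)) != 2L ||
      length(unique(tid)) != 2L || anyDuplicated(paste(fid, tid)))
    stop("sequences must form a complete 2 x 2 factorial set")
  pairs <- expand.grid(train = ids, test = ids, stringsAsFactors = FALSE)
  same_f <- fid[pairs$train] == fid[pairs$test]
  same_t <- tid[pairs$train] == tid[pairs$test]
  keep <- switch(mode,
                 within = same_f & same_t,
                 temporal = same_t & !same_f,
                 spatial = same_f & !same_t,
                 positional = !same_f & !same_t)
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "out.attrs") <- NULL
  out
}

.prep_cols <- function(trace, prep_window) {
  cols <- which(trace$window_starts >= prep_window[1] &
                  trace$window_starts + trace$width <= prep_window[2])
  if (!length(cols)) stop("preparation window not covered by trace grid")
  cols
}

#' Mean press probabilities over the preparation window
#'
#' @param trace A `"probability_trace"`.
#' @param prep_window Half-open window (ms) before the go cue; default the
#'   final 1 s of preparation, `[-1000, 0)`.
#' @return Numeric vector of 5 mean probabilities (sums to 1).
#' @export
prep_window_probs <- function(trace, prep_window = c(-1000, 0)) {
  rowMeans(trace$probs[, .prep_cols(trace, prep_window), drop = FALSE])
}

#' Per-trial competitive-queuing distance
#'
#' For each pair of consecutive presses in the variant, takes the median over
#' preparation windows of the posterior difference `p_k - p_(k+1)`; the trial
#' distance is the mean of those pair medians (`"pair_median_mean"`, default)
#' or the median of the pooled per-window differences (`"pooled_median"`).
#' Positive d means the press probabilities are ordered by upcoming serial
#' position. The `presses_2_5` variant drops press 1, whose finger and timing
#' are shared across all sequences.
#'
#' @param trace A `"probability_trace"`.
#' @param prep_window Preparation window (ms), default `[-1000, 0)`.
#' @param variant `"presses_1_5"` (pairs 1-2 .. 4-5) or `"presses_2_5"`
#'   (pairs 2-3 .. 4-5).
#' @param aggregation Aggregation of pair x window differences (see above).
#' @return List with `d`, named `pair_medians`, `variant` and `aggregation`.
#' @export
cq_distance <- function(trace, prep_window = c(-1000, 0),
                        variant = c("presses_1_5", "presses_2_5"),
                        aggregation = c("pair_median_mean", "pooled_median")) {
  variant <- match.arg(variant)
  aggregation <- match.arg(aggregation)
  cols <- .prep_cols(trace, prep_window)
  first <- if (variant == "presses_1_5") 1L else 2L
  ks <- first:4
  diffs <- lapply(ks, function(k)
    trace$probs[k, cols] - trace$probs[k + 1, cols])
  pair_medians <- vapply(diffs, stats::median, numeric(1))
  names(pair_medians) <- paste0("d", ks, ks + 1)
  d <- if (aggregation == "pair_median_mean") mean(pair_medians) else
    stats::median(unlist(diffs))
  list(d = d, pair_medians = pair_medians, variant = variant,
       aggregation = aggregation)
}

#' OLS slope of each press probability over the preparation window
#'
#' The temporal-proximity account predicts positive slopes (probabilities
#' rising toward each press); stable competitive queuing predicts slopes
#' indistinguishable from 0.
#'
#' @inheritParams cq_distance
#' @return Numeric vector of 5 slopes in probability per second.
#' @export
probability_slope <- function(trace, prep_window = c(-1000, 0)) {
  cols <- .prep_cols(trace, prep_window)
  if (length(cols) < 2L) stop("need at least 2 windows for a slope")
  t_s <- (trace$window_starts[cols] + trace$width / 2) / 1000
  tc <- t_s - mean(t_s)
  denom <- sum(tc^2)
  as.numeric(trace$probs[, cols, drop = FALSE] %*% tc / denom)
}

#' Correlation of training patterns with every time window
#'
#' Entry (k, w) is the Pearson correlation across channels between the model's
#' class-k training mean and the window-w feature vector. Under a slow-drift
#' account the rows would rise smoothly toward their presses; under CQ they
#' need not. Zero-variance windows yield `NA`.
#'
#' @param model A [fit_gaussian_linear()] model.
#' @param epoch An `"epoch_recording"`.
#' @param grid A [window_grid()].
#' @return K x windows correlation matrix.
#' @export
pattern_similarity <- function(model, epoch, grid) {
  wf <- extract_window_means(epoch, grid)
  out <- matrix(NA_real_, model$K, nrow(wf$X))
  for (k in seq_len(model$K)) {
    mu <- model$means[k, ]
    if (stats::sd(mu) == 0) next
    sx <- apply(wf$X, 1, stats::sd)
    ok <- sx > 0
    out[k, ok] <- suppressWarnings(as.numeric(stats::cor(mu, t(wf$X[ok, ,
                                                                    drop = FALSE]))))
  }
  out
}

#' Decoded probability at each press, against chance
#'
#' From cross-validated decoding (so no press window is scored by a model
#' trained on its own trial): the posterior of the true press in the window
#' ending at its onset, averaged over trials, with a one-tailed t test against
#' chance (1/K = 0.2), Bonferroni-corrected over the five presses.
#'
#' @param cv Result of [crossval_decode()].
#' @param alpha Significance level after correction.
#' @return data.frame with per-press `mean_prob`, `t`, `p_raw`, `p_adj`,
#'   `significant`.
#' @export
production_peaks <- function(cv, alpha = 0.05) {
  ok <- stats::complete.cases(cv$press_prob)
  probs <- cv$press_prob[ok, , drop = FALSE]
  res <- lapply(1:5, function(k) {
    tt <- stats::t.test(probs[, k], mu = 0.2, alternative = "greater")
    data.frame(press = k, mean_prob = mean(probs[, k]),
               t = unname(tt$statistic), p_raw = tt$p.value)
  })
  out <- do.call(rbind, res)
  out$p_adj <- pmin(1, out$p_raw * 5)
  out$significant <- out$p_adj < alpha
  out
}

#' Run the CQ decoding analysis on a session
#'
#' For every ordered train/test pair of the chosen transfer regime: fit the
#' Gaussian-linear classifier on the press-onset windows of the training
#' sequence's correct trials (press-position labels), decode the preparation
#' grid of every correct test trial, and compute the per-trial preparation
#' probabilities and CQ distance. The session aggregate is the mean per-trial
#' d across all pairs and trials.
#'
#' @param dataset A `"cq_dataset"`.
#' @param mode Transfer regime, see [pair_transfer()].
#' @param variant,aggregation Passed to [cq_distance()].
#' @param prep_window Preparation window (ms).
#' @param lambda Classifier shrinkage.
#' @param delta Training-window width (ms).
#' @return An object of class `"cq_session_result"`: `per_trial` (data.frame
#'   with pair ids, trial index, d, pair medians d12..d45 and mean
#'   preparation probabilities p1..p5), `aggregate` (mean d), `per_pair`
#'   summary, `mode`, `variant`.
#' @export
run_cq_analysis <- function(dataset, mode = "within",
                            variant = "presses_1_5",
                            aggregation = "pair_median_mean",
                            prep_window = c(-1000, 0),
                            lambda = 0.1, delta = 10) {
  pairs <- pair_transfer(dataset$sequences, mode)
  press_X <- .dataset_press_features(dataset, delta)
  gridf <- .dataset_grid_features(dataset)
  tab <- dataset$trials
  rows <- list()
  for (pi in seq_len(nrow(pairs))) {
    tr_id <- pairs$train[pi]; te_id <- pairs$test[pi]
    train <- which(tab$sequence_id == tr_id & tab$correct_fingers)
    test <- which(tab$sequence_id == te_id & tab$correct_fingers)
    if (length(train) < 2L) stop("too few correct trials in ", tr_id)
    Xtr <- do.call(rbind, lapply(train, function(i) press_X[i, , ]))
    model <- fit_gaussian_linear(Xtr, rep(1:5, length(train)), lambda)
    for (i in test) {
      trace <- probability_trace(t(posterior(model, gridf$X[i, , ])),
                                 gridf$window_starts, gridf$width, te_id)
      cq <- cq_distance(trace, prep_window, variant, aggregation)
      pm <- cq_distance(trace, prep_window, "presses_1_5", aggregation)
      rows[[length(rows) + 1L]] <- data.frame(
        train = tr_id, test = te_id, trial = i, d = cq$d,
        t(pm$pair_medians),
        t(stats::setNames(prep_window_probs(trace, prep_window),
                          paste0("p", 1:5))),
        t(stats::setNames(probability_slope(trace, prep_window),
                          paste0("slope", 1:5))))
    }
  }
  per_trial <- do.call(rbind, rows)
  per_pair <- stats::aggregate(d ~ train + test, per_trial, mean)
  structure(list(per_trial = per_trial,
                 aggregate = mean(per_trial$d),
                 per_pair = per_pair,
                 mode = mode, variant = variant,
                 prep_window = prep_window),
            class = "cq_session_result")
}

#' @export
print.cq_session_result <- function(x, ...) {
  cat(sprintf("<cq_session_result> mode %s, variant %s: aggregate d = %.4f over %d trials\n",
              x$mode, x$variant, x$aggregate, nrow(x$per_trial)))
  invisible(x)
}

#' Percentile bootstrap confidence interval for a mean
#'
#' @param x Numeric vector (e.g. per-trial CQ distances).
#' @param n_boot Bootstrap resamples.
#' @param conf Confidence level.
#' @param seed Seed.
#' @return List with `mean`, `lower`, `upper`, `conf`.
#' @export
bootstrap_ci <- function(x, n_boot = 2000, conf = 0.95, seed = 1) {
  set.seed(seed)
  n <- length(x)
  boots <- vapply(seq_len(n_boot), function(b)
    mean(x[sample.int(n, n, replace = TRUE)]), numeric(1))
  qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE)
  list(mean = mean(x), lower = qs[1], upper = qs[2], conf = conf)
}

#' Link CQ strength to behavioural accuracy
#'
#' Across participants: one-tailed Pearson correlation between per-subject CQ
#' aggregates and error metrics under the directional hypothesis that stronger
#' CQ accompanies fewer errors, plus a median-split two-sample t test
#' (accurate > inaccurate CQ, one-tailed). Within participants: per-subject
#' trial-by-trial correlations of d with temporal error.
#'
#' @param subject_d Per-subject aggregate CQ distances.
#' @param subject_err Per-subject error metric (finger error rate or temporal
#'   error).
#' @param trial_d Optional list (one per subject) of per-trial d values.
#' @param trial_err Optional list of matching per-trial temporal errors.
#' @return List with `across` (r, t, p), `split` (group means, t, p), and
#'   `per_subject` (data.frame of trial-level r and p, or NULL).
#' @export
cq_behavior_link <- function(subject_d, subject_err,
                             trial_d = NULL, trial_err = NULL) {
  if (length(subject_d) < 3L) stop("need >= 3 subjects")
  across <- correlate(subject_d, subject_err, tail = "one",
                      direction = "negative")
  grp <- median_split(subject_err)
  tt <- stats::t.test(subject_d[grp$low], subject_d[grp$high],
                      alternative = "greater")
  split <- list(mean_accurate = mean(subject_d[grp$low]),
                mean_inaccurate = mean(subject_d[grp$high]),
                t = unname(tt$statistic), p = tt$p.value)
  per_subject <- NULL
  if (!is.null(trial_d)) {
    stopifnot(length(trial_d) == length(trial_err))
    per_subject <- do.call(rbind, lapply(seq_along(trial_d), function(s) {
      ct <- correlate(trial_d[[s]], trial_err[[s]], tail = "one",
                      direction = "negative")
      data.frame(subject = s, r = ct$r, p = ct$p)
    }))
  }
  list(across = across, split = split, per_subject = per_subject)
}
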