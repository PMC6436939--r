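# Ground-truth-known generator of multichannel neural-like and EMG-like
# epochs for the cued sequence task: graded preparatory superposition of
# press-specific spatial patterns, phasic press-locked pulses, factorized
# finger / interval / position codes, and configurable confounds.

#' Build a factorized spatial pattern basis
#'
#' Draws three families of five channel patterns (finger identity, preceding
#' target interval, ordinal position). Within each family the vectors are
#' Gram-Schmidt orthonormalized. The composite pattern for press k of a
#' sequence is the mixture `mix[1]*finger + mix[2]*interval + mix[3]*position`,
#' renormalized to unit length; the mixture weights therefore control which
#' code the transfer analyses can pick up.
#'
#' @param n_channels Number of channels (>= 15 unless `support` is given;
#'   the support must be able to hold 5 orthonormal vectors per family).
#' @param mix Nonnegative weights `(finger, interval, position)` summing to 1.
#' @param seed Integer seed; the basis is reproducible.
#' @param support Optional integer vector of channel indices to which all
#'   patterns are confined (>= 5 channels); used for planted-support
#'   searchlight recovery studies.
#' @return An object of class `"pattern_basis"` with matrices
#'   `finger_patterns`, `interval_patterns`, `position_patterns` (5 x
#'   n_channels each), the `mix` weights and the `seed`.
#' @export
make_pattern_basis <- function(n_channels, mix = c(1, 1, 1) / 3, seed = 1,
                               support = NULL) {
  if (any(mix < 0)) stop("mix weights must be nonnegative")
  if (abs(sum(mix) - 1) > 1e-8) stop("mix weights must sum to 1")
  if (is.null(support)) {
    if (n_channels < 15L)
      stop("need at least 15 channels to orthogonalize 3 families of 5 patterns")
    support <- seq_len(n_channels)
  } else {
    support <- as.integer(support)
    if (length(support) < 5L || any(support < 1L) || any(support > n_channels))
      stop("support must name >= 5 valid channels")
  }
  set.seed(seed)
  draw_family <- function() {
    m <- matrix(0, 5, n_channels)
    raw <- matrix(stats::rnorm(length(support) * 5), length(support), 5)
    m[, support] <- t(qr.Q(qr(raw)))  # orthonormal rows on the support
    m
  }
  structure(list(n_channels = as.integer(n_channels),
                 finger_patterns = draw_family(),
                 interval_patterns = draw_family(),
                 position_patterns = draw_family(),
                 mix = as.numeric(mix),
                 support = support,
                 seed = as.integer(seed)),
            class = "pattern_basis")
}

#' Composite press patterns for a sequence
#'
#' @param basis A [make_pattern_basis()] object.
#' @param spec A [sequence_spec()].
#' @param fingers Optional produced finger order (defaults to the cued order);
#'   used for transposition-error trials.
#' @return 5 x n_channels matrix; row k is the unit-norm composite pattern
#'   active before press k.
#' @export
composite_patterns <- function(basis, spec, fingers = spec$finger_order) {
  iv_class <- match(spec$interval_order, cq_target_intervals)
  out <- matrix(0, 5, basis$n_channels)
  for (k in 1:5) {
    v <- basis$mix[1] * basis$finger_patterns[fingers[k], ] +
      basis$mix[2] * basis$interval_patterns[iv_class[k], ] +
      basis$mix[3] * basis$position_patterns[k, ]
    n <- sqrt(sum(v^2))
    out[k, ] <- if (n > 0) v / n else v
  }
  out
}

#' Generator parameters
#'
#' Tunable parameters of the epoch generator. Defaults encode the study
#' conditions: 1000 samples/s, a preparation period drawn uniformly from
#' 1.8-2.2 s, a geometric preparatory gradient `0.3 * 0.75^(0:4)` (peak 0.3 x
#' the unit production pulse), Gaussian production pulses of SD 50 ms, sensor
#' noise SD 1 (graded, non-saturated preparatory posteriors), multiplicative
#' timing noise SD 0.2 and a 2% adjacent-transposition rate.
#'
#' @param sample_rate Samples per second.
#' @param epoch_window Epoch extent (ms) around the go cue.
#' @param prep_range Range (ms) of the uniformly drawn cue-to-go duration.
#' @param pulse_sd SD (ms) of the Gaussian press-locked envelope.
#' @param prep_gradient Five nonnegative weights g1..g5 applied to the press
#'   patterns during preparation.
#' @param noise_sd SD of i.i.d. Gaussian sensor noise (amplitude units).
#' @param drift_phi AR(1) coefficient of the slow common drift (per sample).
#' @param drift_sd Stationary SD of the drift; 0 disables drift.
#' @param timing_noise_sd SD of the multiplicative noise on produced intervals
#'   (truncated at +/- 3 SD).
#' @param finger_swap_prob Probability that one adjacent pair among presses
#'   2-5 is transposed (press 1 is never moved).
#' @param emg_prep_amp Tonic preparatory amplitude of the first press's muscle
#'   pattern in the EMG generator.
#' @return An object of class `"generator_params"`.
#' @export
generator_params <- function(sample_rate = 1000,
                             epoch_window = c(-2800, 8500),
                             prep_range = c(1800, 2200),
                             pulse_sd = 50,
                             prep_gradient = 0.3 * 0.75^(0:4),
                             noise_sd = 1.0,
                             drift_phi = 0.999,
                             drift_sd = 0,
                             timing_noise_sd = 0.2,
                             finger_swap_prob = 0.02,
                             emg_prep_amp = 0.3) {
  stopifnot(length(prep_gradient) == 5L, all(is.finite(prep_gradient)),
            all(prep_gradient >= 0),
            drift_phi >= 0, drift_phi < 1,
            finger_swap_prob >= 0, finger_swap_prob <= 1,
            epoch_window[1] < 0, epoch_window[2] > 0)
  structure(list(sample_rate = sample_rate, epoch_window = epoch_window,
                 prep_range = prep_range, pulse_sd = pulse_sd,
                 prep_gradient = prep_gradient, noise_sd = noise_sd,
                 drift_phi = drift_phi, drift_sd = drift_sd,
                 timing_noise_sd = timing_noise_sd,
                 finger_swap_prob = finger_swap_prob,
                 emg_prep_amp = emg_prep_amp),
            class = "generator_params")
}

# Shared per-trial behavioural draws. RNG draw order is part of the format:
# (1) transposition uniform + pair choice, (2) preparation duration,
# (3) five timing-noise deviates. Tests replay this order to audit the
# generator with an independent RNG.
.draw_trial_behaviour <- function(spec, params) {
  swap <- stats::runif(1) < params$finger_swap_prob
  pair <- if (swap) sample(2:4, 1) else NA_integer_
  prep_dur <- stats::runif(1, params$prep_range[1], params$prep_range[2])
  z <- pmin(3, pmax(-3, stats::rnorm(5)))
  mult <- 1 + params$timing_noise_sd * z
  fingers <- spec$finger_order
  if (swap) fingers[c(pair, pair + 1)] <- fingers[c(pair + 1, pair)]
  list(swap = swap, pair = pair, prep_dur = prep_dur, mult = mult,
       fingers = fingers,
       press_times = cumsum(spec$interval_order * mult))
}

.sample_index <- function(t_ms, t0, fs) t0 + round(t_ms * fs / 1000)

# Deterministic signal + events for one trial; noise added by callers.
.assemble_epoch <- function(patterns, prep_vec, beh, params, n_channels) {
  fs <- params$sample_rate
  n_samples <- round(diff(params$epoch_window) * fs / 1000) + 1L
  t0 <- round(-params$epoch_window[1] * fs / 1000) + 1L  # sample of go (t = 0)
  data <- matrix(0, n_channels, n_samples)
  cue_t <- -beh$prep_dur
  i_cue <- max(1L, .sample_index(cue_t, t0, fs))
  data[, i_cue:(t0 - 1L)] <- data[, i_cue:(t0 - 1L)] + prep_vec
  half <- round(5 * params$pulse_sd * fs / 1000)
  sd_samp <- params$pulse_sd * fs / 1000
  for (k in 1:5) {
    ip <- .sample_index(beh$press_times[k], t0, fs)
    lo <- max(1L, ip - half); hi <- min(n_samples, ip + half)
    env <- exp(-((lo:hi - ip)^2) / (2 * sd_samp^2))
    data[, lo:hi] <- data[, lo:hi] + outer(patterns[k, ], env)
  }
  list(data = data, t0 = t0, n_samples = n_samples, cue = cue_t)
}

#' Simulate one multichannel trial
#'
#' The generated signal is a constant superposition
#' `sum_k g_k * pattern_k` from the sequence cue to the go cue, plus a
#' unit-amplitude Gaussian-envelope pulse of each press pattern at its press
#' onset, plus i.i.d. Gaussian sensor noise and (optionally) a spatially
#' rank-1 AR(1) common drift. Press times follow the target intervals with
#' multiplicative timing noise; with probability `finger_swap_prob` one
#' adjacent pair of presses 2-5 is transposed and the trial is marked as a
#' finger error.
#'
#' @param spec The cued [sequence_spec()].
#' @param basis A [make_pattern_basis()] object.
#' @param params A [generator_params()] object.
#' @param seed Integer seed; the same seed reproduces the epoch bit for bit.
#' @return An object of class `"epoch_recording"`: `data` (channels x
#'   samples), `t0` (sample index of go), `fs`, `events` (cue, go, presses in
#'   ms), the [trial_result()] and a `ground_truth` list.
#' @export
simulate_trial <- function(spec, basis, params = generator_params(), seed = 1) {
  set.seed(seed)
  beh <- .draw_trial_behaviour(spec, params)
  patterns <- composite_patterns(basis, spec, beh$fingers)
  prep_vec <- colSums(params$prep_gradient * composite_patterns(basis, spec))
  ep <- .assemble_epoch(patterns, prep_vec, beh, params, basis$n_channels)
  data <- ep$data
  if (params$noise_sd > 0)
    data <- data + matrix(stats::rnorm(length(data), 0, params$noise_sd),
                          nrow(data), ncol(data))
  if (params$drift_sd > 0) {
    innov <- stats::rnorm(ep$n_samples)
    z <- as.numeric(stats::filter(
      innov * params$drift_sd * sqrt(1 - params$drift_phi^2),
      params$drift_phi, method = "recursive",
      init = stats::rnorm(1, 0, params$drift_sd)))
    u <- stats::rnorm(basis$n_channels)
    u <- u / sqrt(sum(u^2))
    data <- data + outer(u, z)
  }
  trial <- trial_result(spec$id, beh$fingers, beh$press_times, spec = spec)
  structure(list(data = data, t0 = ep$t0, fs = params$sample_rate,
                 epoch_window = params$epoch_window,
                 events = list(cue = ep$cue, go = 0,
                               presses = beh$press_times),
                 sequence_id = spec$id, trial = trial,
                 ground_truth = list(g = params$prep_gradient,
                                     patterns = patterns,
                                     prep_vec = prep_vec,
                                     swapped = beh$swap,
                                     swap_pair = beh$pair,
                                     timing_mult = beh$mult)),
            class = "epoch_recording")
}

# Synthetic muscle synergy basis for 4 EMG channels (FCR, APB, ADM, FDI
# roles). Finger 1 loads channel 1; fingers 2-5 sit at 60 degrees from finger
# 1 and are mutually orthogonal (tetrahedral construction), so presses 2-5
# are exactly exchangeable for the classifier.
#' Muscle patterns used by the EMG generator
#' @return 5 x 4 matrix of unit-norm muscle patterns, one row per finger.
#' @export
muscle_patterns <- function() {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  m <- rbind(c(1, 0, 0, 0),
             cbind(0.5, sqrt(3) / 2 * v))
  rownames(m) <- paste0("finger", 1:5)
  colnames(m) <- c("FCR", "APB", "ADM", "FDI")
  m
}

#' Simulate one 4-channel EMG trial
#'
#' During preparation only the first press's muscle pattern is tonically
#' active (amplitude `emg_prep_amp`); during production each press emits its
#' muscle pattern phasically, with the same pulse shape and noise model as the
#' neural generator.
#'
#' @inheritParams simulate_trial
#' @return An `"epoch_recording"` with 4 channels.
#' @export
simulate_emg <- function(spec, params = generator_params(), seed = 1) {
  set.seed(seed)
  beh <- .draw_trial_behaviour(spec, params)
  mus <- muscle_patterns()
  patterns <- mus[beh$fingers, , drop = FALSE]
  prep_vec <- params$emg_prep_amp * mus[spec$finger_order[1], ]
  ep <- .assemble_epoch(patterns, prep_vec, beh, params, 4L)
  data <- ep$data
  if (params$noise_sd > 0)
    data <- data + matrix(stats::rnorm(length(data), 0, params$noise_sd),
                          nrow(data), ncol(data))
  trial <- trial_result(spec$id, beh$fingers, beh$press_times, spec = spec)
  structure(list(data = data, t0 = ep$t0, fs = params$sample_rate,
                 epoch_window = params$epoch_window,
                 events = list(cue = ep$cue, go = 0,
                               presses = beh$press_times),
                 sequence_id = spec$id, trial = trial,
                 ground_truth = list(prep_amp = params$emg_prep_amp,
                                     patterns = patterns,
                                     swapped = beh$swap)),
            class = "epoch_recording")
}

.derive_trial_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 104729 * i) %% 2147483647)
}

# Subject-level seed stream: a different multiplier than the trial stream so
# that subject x trial seed grids never collide across subjects.
.derive_subject_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 15485863 * i) %% 2147483647)
}

#' Simulate a full session
#'
#' Applies [simulate_trial()] (or [simulate_emg()]) to every scheduled trial
#' with per-trial seeds derived from `seed`. With `compact = TRUE` each epoch
#' is immediately reduced to the window features the decoding pipeline
#' consumes (press-onset training windows plus a preparation-period window
#' grid) and the raw epoch is discarded, keeping memory flat in the number of
#' trials.
#'
#' @param schedule A [schedule_session()] object.
#' @param sequences The sequence set the schedule refers to.
#' @param basis A [make_pattern_basis()] object (ignored for
#'   `modality = "emg"`).
#' @param params A [generator_params()] object.
#' @param seed Session seed.
#' @param modality `"neural"` (uses `basis`) or `"emg"` (4 channels).
#' @param compact If `TRUE`, store window features instead of raw epochs.
#' @param grid Window grid for the compact preparation features (default
#'   non-overlapping 10-ms windows over [-2000, 0) ms).
#' @param delta Training-window width (ms) for the compact press features.
#' @return An object of class `"cq_dataset"`: `trials` (data.frame with trial,
#'   block, sequence_id, correct_fingers, seed), `results` (list of
#'   [trial_result()]), and either `epochs` or `features`.
#' @export
simulate_session <- function(schedule, sequences, basis = NULL,
                             params = generator_params(), seed = 1,
                             modality = c("neural", "emg"),
                             compact = FALSE,
                             grid = window_grid(-2000, 0, 10),
                             delta = 10) {
  modality <- match.arg(modality)
  if (modality == "neural" && is.null(basis))
    stop("basis required for neural simulation")
  tab <- schedule_trials(schedule)
  n <- nrow(tab)
  n_channels <- if (modality == "neural") basis$n_channels else 4L
  epochs <- if (!compact) vector("list", n) else NULL
  results <- vector("list", n)
  press_X <- if (compact) array(NA_real_, c(n, 5, n_channels)) else NULL
  grid_X <- if (compact)
    array(NA_real_, c(n, length(grid$starts), n_channels)) else NULL
  tab$correct_fingers <- NA
  tab$seed <- NA_integer_
  for (i in seq_len(n)) {
    s <- .derive_trial_seed(seed, i)
    spec <- sequences[[tab$sequence_id[i]]]
    ep <- if (modality == "neural")
      simulate_trial(spec, basis, params, seed = s)
    else simulate_emg(spec, params, seed = s)
    results[[i]] <- ep$trial
    tab$correct_fingers[i] <- isTRUE(ep$trial$correct_fingers)
    tab$seed[i] <- s
    if (compact) {
      press_X[i, , ] <- press_window_features(ep, delta)
      grid_X[i, , ] <- extract_window_means(ep, grid)$X
    } else {
      epochs[[i]] <- ep
    }
  }
  out <- list(trials = tab, results = results, sequences = sequences,
              params = params, basis = basis, modality = modality,
              seed = as.integer(seed), n_channels = n_channels)
  if (compact) {
    out$features <- list(press_X = press_X, grid_X = grid_X,
                         window_starts = grid$starts, width = grid$width,
                         delta = delta)
  } else {
    out$epochs <- epochs
  }
  structure(out, class = "cq_dataset")
}

#' @export
print.cq_dataset <- function(x, ...) {
  cat(sprintf("<cq_dataset> %d trials, %d channels (%s, %s)\n",
              nrow(x$trials), x$n_channels, x$modality,
              if (is.null(x$epochs)) "compact features" else "raw epochs"))
  invisible(x)
}
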