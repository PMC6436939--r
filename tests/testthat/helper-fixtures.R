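# Shared fixtures: all synthetic, built in code at test time.

# Small, fast generator settings for unit tests (16 channels, short epoch).
test_params <- function(...) {
  generator_params(epoch_window = c(-2400, 7200), ...)
}

test_session <- function(preset = "cq-on", n_channels = 16, n_blocks = 2,
                         reps = 3, seed = 1, params = NULL, support = NULL,
                         sequences = default_sequences()) {
  p <- cq_preset(preset, n_channels = n_channels, seed = seed,
                 support = support)
  if (is.null(params)) {
    params <- test_params(
      prep_gradient = p$params$prep_gradient,
      drift_sd = p$params$drift_sd, drift_phi = p$params$drift_phi)
  }
  schedule <- schedule_session(n_blocks, reps, sequences, seed)
  simulate_session(schedule, sequences, p$basis, params, seed = seed,
                   compact = TRUE)
}

# Pattern basis whose composite patterns are all zero: uninformative data.
zero_basis <- function(n_channels = 16) {
  zeros <- matrix(0, 5, n_channels)
  structure(list(n_channels = as.integer(n_channels),
                 finger_patterns = zeros, interval_patterns = zeros,
                 position_patterns = zeros, mix = c(1, 1, 1) / 3,
                 support = seq_len(n_channels), seed = 0L),
            class = "pattern_basis")
}

# Minimal epoch wrapper for feature-extraction tests.
fake_epoch <- function(data, t0, fs = 1000) {
  structure(list(data = data, t0 = t0, fs = fs,
                 events = list(cue = NA, go = 0, presses = numeric(0)),
                 sequence_id = "X"),
            class = "epoch_recording")
}

# A deterministic probability trace with the given constant column.
constant_trace <- function(p, n_windows = 100, start = -1000, width = 10) {
  probability_trace(matrix(p, length(p), n_windows),
                    seq(start, by = width, length.out = n_windows), width)
}

# Mean Gaussian-envelope factor over the 10 samples preceding a press onset,
# matching the generator's discretization (fs = 1000, pulse SD 50 ms).
press_envelope_factor <- function(delta = 10, pulse_sd = 50) {
  mean(exp(-(seq_len(delta))^2 / (2 * pulse_sd^2)))
}
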