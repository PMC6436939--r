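# Named generator presets used throughout the analyses and tests.

#' Generator presets
#'
#' Bundles a pattern basis and generator parameters for the standard study
#' conditions:
#' \describe{
#'   \item{cq-on}{Equal-thirds finger/interval/position mixture with the
#'     geometric preparatory gradient `0.3 * 0.75^(0:4)` -- the CQ-positive
#'     condition.}
#'   \item{cq-off}{Same basis, but a flat preparatory gradient (all presses
#'     equally pre-activated): no queuing structure to recover.}
#'   \item{drift-only}{No preparatory patterns at all (gradient 0) plus a
#'     strong slow rank-1 AR(1) common drift -- the temporal-proximity
#'     confound condition.}
#'   \item{finger-only}{Pure finger-identity code, `mix = (1, 0, 0)`.}
#'   \item{position-only}{Pure ordinal-position code, `mix = (0, 0, 1)`.}
#' }
#'
#' @param name Preset name.
#' @param n_channels Number of channels (default 64).
#' @param seed Seed for the pattern basis.
#' @param support Optional planted channel support passed to
#'   [make_pattern_basis()].
#' @return List with `basis` and `params`.
#' @export
cq_preset <- function(name = c("cq-on", "cq-off", "drift-only",
                               "finger-only", "position-only"),
                      n_channels = 64, seed = 1, support = NULL) {
  name <- match.arg(name)
  mix <- switch(name,
                "finger-only" = c(1, 0, 0),
                "position-only" = c(0, 0, 1),
                c(1, 1, 1) / 3)
  basis <- make_pattern_basis(n_channels, mix, seed, support = support)
  params <- switch(name,
    "cq-off" = generator_params(prep_gradient = rep(0.3, 5)),
    "drift-only" = generator_params(prep_gradient = rep(0, 5),
                                    drift_sd = 1, drift_phi = 0.999),
    generator_params())
  list(basis = basis, params = params, name = name)
}

#' Simulate a standard session under a preset
#'
#' Convenience wrapper: builds the default 240-trial schedule (10 blocks x 6
#' reps x 4 sequences) over `sequences`, simulates it compactly under the
#' preset, and returns the dataset.
#'
#' @param preset A [cq_preset()] (or preset name).
#' @param sequences Sequence set (default [default_sequences()]).
#' @param seed Session seed (drives both schedule and epochs).
#' @param n_blocks,reps Schedule size.
#' @param grid Preparation window grid stored in the compact features.
#' @return A compact `"cq_dataset"`.
#' @export
simulate_preset_session <- function(preset, sequences = default_sequences(),
                                    seed = 1, n_blocks = 10, reps = 6,
                                    grid = window_grid(-2000, 0, 10)) {
  if (is.character(preset)) preset <- cq_preset(preset, seed = seed)
  schedule <- schedule_session(n_blocks, reps, sequences, seed)
  simulate_session(schedule, sequences, preset$basis, preset$params,
                   seed = seed, compact = TRUE, grid = grid)
}
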