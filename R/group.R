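# Subject-level replication: simulate a group of synthetic participants and
# summarize each subject's session with the CQ statistics. Aggregate claims
# about the CQ distance are made across subjects, not across trials of one
# session, because every trial of a sequence is decoded by the same fitted
# classifier: the classifier's class-mean sampling error induces a small,
# session-fixed bias in d that trial-level resampling cannot see.

#' Simulate and analyse a group of synthetic subjects
#'
#' Each subject gets its own randomly drawn sequence set (first press shared,
#' positions 2-5 deranged), 240-trial session (10 blocks x 6 repetitions),
#' pattern basis and noise realization, and is summarized by the whole-head
#' analysis of [run_cq_analysis()].
#'
#' @param preset Preset name for [cq_preset()] (ignored for EMG).
#' @param n_subjects Number of synthetic subjects.
#' @param seed Group seed; per-subject seeds are derived from it.
#' @param modality `"neural"` or `"emg"`.
#' @param n_channels Channels for the neural generator.
#' @param mode,variant Passed to [run_cq_analysis()].
#' @param n_blocks,reps Session size per subject.
#' @return data.frame with one row per subject: aggregate `d`, mean
#'   preparation probabilities `p1..p5`, mean preparation slopes
#'   `slope1..slope5` (probability per second), mean absolute `temporal_error`
#'   (percent) and the `finger_error` rate.
#' @export
group_cq_study <- function(preset = "cq-on", n_subjects = 6, seed = 1,
                           modality = c("neural", "emg"), n_channels = 64,
                           mode = "within", variant = "presses_1_5",
                           n_blocks = 10, reps = 6) {
  modality <- match.arg(modality)
  rows <- lapply(seq_len(n_subjects), function(i) {
    ss <- .derive_subject_seed(seed, i)
    seqs <- random_sequence_set(ss)
    sch <- schedule_session(n_blocks, reps, seqs, ss)
    ds <- if (modality == "neural") {
      p <- cq_preset(preset, n_channels = n_channels, seed = ss)
      simulate_session(sch, seqs, p$basis, p$params, seed = ss,
                       compact = TRUE)
    } else {
      simulate_session(sch, seqs, params = generator_params(), seed = ss,
                       modality = "emg", compact = TRUE)
    }
    res <- run_cq_analysis(ds, mode, variant)
    errs <- vapply(seq_along(ds$results), function(t)
      temporal_error(ds$results[[t]],
                     ds$sequences[[ds$trials$sequence_id[t]]])$abs_pct,
      numeric(1))
    cbind(data.frame(subject = i, d = res$aggregate),
          t(colMeans(res$per_trial[paste0("p", 1:5)])),
          t(colMeans(res$per_trial[paste0("slope", 1:5)])),
          data.frame(temporal_error = mean(errs, na.rm = TRUE),
                     finger_error = mean(!ds$trials$correct_fingers)))
  })
  do.call(rbind, rows)
}
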