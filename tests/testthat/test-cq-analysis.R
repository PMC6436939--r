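test_that("transfer pairing follows the factorial relations", {
  s <- default_sequences()
  expect_equal(pair_transfer(s, "within"),
               data.frame(train = names(s), test = names(s)))
  tem <- pair_transfer(s, "temporal")
  expect_equal(tem$test[tem$train == "F1T1"], "F2T1")

  # exhaustive relation oracle over all 16 ordered pairs
  fid <- substr(names(s), 1, 2); tid <- substr(names(s), 3, 4)
  names(fid) <- names(tid) <- names(s)
  for (mode in c("within", "temporal", "spatial", "positional")) {
    got <- pair_transfer(s, mode)
    expect_equal(nrow(got), 4L)
    oracle <- list()
    for (a in names(s)) for (b in names(s)) {
      keep <- switch(mode,
                     within = a == b,
                     temporal = tid[a] == tid[b] && fid[a] != fid[b],
                     spatial = fid[a] == fid[b] && tid[a] != tid[b],
                     positional = fid[a] != fid[b] && tid[a] != tid[b])
      if (keep) oracle[[length(oracle) + 1L]] <- c(a, b)
    }
    expect_setequal(paste(got$train, got$test),
                    vapply(oracle, paste, "", collapse = " "))
  }
  expect_error(pair_transfer(s[1:3], "within"), "factorial")
})

test_that("preparation-window probabilities average the right columns", {
  expect_equal(prep_window_probs(constant_trace(rep(0.2, 5))), rep(0.2, 5))
  p <- c(0.4, 0.25, 0.2, 0.1, 0.05)
  expect_equal(prep_window_probs(constant_trace(p)), p)

  set.seed(2)
  probs <- matrix(runif(5 * 150), 5, 150)
  tr <- probability_trace(probs, seq(-1400, by = 10, length.out = 150), 10)
  got <- prep_window_probs(tr, c(-1000, 0))
  # loop oracle: windows fully inside [-1000, 0)
  cols <- which(tr$window_starts >= -1000 & tr$window_starts + 10 <= 0)
  expect_equal(got, rowMeans(probs[, cols]), tolerance = 1e-12)
  expect_error(prep_window_probs(tr, c(-3000, -2000)), "not covered")
})

test_that("cq distance aggregates pair medians as specified", {
  p <- c(0.4, 0.25, 0.2, 0.1, 0.05)
  tr <- constant_trace(p)
  full <- cq_distance(tr)
  expect_equal(unname(full$pair_medians), c(0.15, 0.05, 0.10, 0.05))
  expect_equal(full$d, 0.0875)
  late <- cq_distance(tr, variant = "presses_2_5")
  expect_equal(late$d, mean(c(0.05, 0.10, 0.05)), tolerance = 1e-12)

  expect_equal(cq_distance(constant_trace(rep(0.2, 5)))$d, 0)

  set.seed(3)
  probs <- matrix(runif(500), 5, 100)
  tr <- probability_trace(probs, seq(-1000, by = 10, length.out = 100), 10)
  rev_tr <- probability_trace(probs[5:1, ], tr$window_starts, 10)
  expect_equal(cq_distance(rev_tr)$d, -cq_distance(tr)$d)  # antisymmetry
  shift <- probability_trace(probs + 0.37, tr$window_starts, 10)
  expect_equal(cq_distance(shift)$d, cq_distance(tr)$d, tolerance = 1e-12)

  pooled <- cq_distance(tr, aggregation = "pooled_median")
  diffs <- as.numeric(probs[1:4, ] - probs[2:5, ])
  expect_equal(pooled$d, median(diffs))
})

test_that("probability slopes match the closed-form OLS oracle", {
  expect_equal(probability_slope(constant_trace(runif(5))), rep(0, 5))

  starts <- seq(-1000, -10, by = 10)
  t_mid <- (starts + 5) / 1000
  lin <- probability_trace(rbind(0.1 + 0.05 * t_mid, 0.2 - 0.02 * t_mid,
                                 matrix(0.2, 3, 100)), starts, 10)
  expect_equal(probability_slope(lin)[1:2], c(0.05, -0.02), tolerance = 1e-10)

  set.seed(4)
  noisy <- probability_trace(matrix(runif(500), 5, 100), starts, 10)
  got <- probability_slope(noisy)
  for (k in 1:5) {       # normal-equations oracle
    beta <- coef(lm(noisy$probs[k, ] ~ t_mid))[2]
    expect_equal(got[k], unname(beta), tolerance = 1e-10)
  }
})

test_that("pattern similarity is the channel-wise Pearson correlation", {
  set.seed(5)
  X <- matrix(rnorm(100), 25, 4)
  y <- rep(1:5, 5)
  m <- fit_gaussian_linear(X, y, lambda = 0.3)
  ep <- fake_epoch(matrix(m$means[2, ], 4, 50), t0 = 26)
  sim <- pattern_similarity(m, ep, window_grid(-20, 20, 10))
  expect_equal(sim[2, ], rep(1, 4), tolerance = 1e-12)

  set.seed(6)
  ep2 <- fake_epoch(matrix(rnorm(4 * 50), 4, 50), t0 = 26)
  sim2 <- pattern_similarity(m, ep2, window_grid(-20, 20, 10))
  wf <- extract_window_means(ep2, window_grid(-20, 20, 10))
  for (k in 1:5) for (w in 1:4)
    expect_equal(sim2[k, w], cor(m$means[k, ], wf$X[w, ]), tolerance = 1e-12)
})

test_that("production peaks exceed chance only for informative data", {
  set.seed(7)
  null_cv <- list(press_prob = matrix(0.2 + rnorm(500, 0, 0.01), 100, 5))
  pk <- production_peaks(null_cv)
  expect_false(any(pk$significant))
  expect_equal(mean(pk$mean_prob), 0.2, tolerance = 0.01)

  hi_cv <- list(press_prob = matrix(pmin(0.999, 0.9 + rnorm(500, 0, 0.02)),
                                    100, 5))
  pk2 <- production_peaks(hi_cv)
  expect_true(all(pk2$significant))
  expect_true(all(pk2$mean_prob > 0.8))
})

test_that("chance-only sessions reject at the nominal rate", {
  s <- default_sequences()["F1T1"]
  params <- test_params(finger_swap_prob = 0)
  pvals <- unlist(lapply(1:25, function(r) {
    sch <- schedule_session(1, 10, s, seed = 100 + r)
    ds <- simulate_session(sch, s, zero_basis(8), params, seed = 100 + r,
                           compact = TRUE)
    cv <- crossval_decode(ds, k_folds = 5, seed = r)
    production_peaks(cv)$p_raw
  }))
  rate <- mean(pvals < 0.05)
  expect_lt(rate, 0.15)          # ~5% nominal; binomial slack at 125 tests
  expect_gt(mean(pvals), 0.25)   # p values not piled near zero
})

test_that("within-sequence analysis recovers the planted gradient order", {
  ds <- test_session("cq-on", n_blocks = 2, reps = 6, seed = 11)
  res <- run_cq_analysis(ds, "within")
  expect_gt(res$aggregate, 0)
  pp <- colMeans(res$per_trial[paste0("p", 1:5)])
  # first press dominates, last press weakest; the full monotone gradient
  # needs study-scale sessions and is asserted in the acceptance suite
  expect_equal(unname(which.max(pp)), 1L)
  expect_equal(unname(which.min(pp)), 5L)
  ci <- bootstrap_ci(res$per_trial$d, seed = 1)
  expect_gt(ci$lower, 0)
  # slopes of a constant preparatory code are centred on zero
  for (k in 2:5) {
    sl <- res$per_trial[[paste0("slope", k)]]
    expect_lt(abs(mean(sl)) / (sd(sl) / sqrt(length(sl))), 3.5)
  }
})

test_that("behaviour link recovers a planted CQ-accuracy association", {
  quality <- seq(0, 1, length.out = 6)   # 6 synthetic subjects
  subj <- lapply(seq_along(quality), function(i) {
    q <- quality[i]
    p <- cq_preset("cq-on", n_channels = 16, seed = 30 + i)
    params <- test_params(
      prep_gradient = 0.3 * (0.9 - 0.4 * q)^(0:4),  # steeper when skilled
      timing_noise_sd = 0.3 - 0.2 * q,
      finger_swap_prob = 0)
    seqs <- random_sequence_set(30 + i)
    sch <- schedule_session(2, 3, seqs, seed = 30 + i)
    ds <- simulate_session(sch, seqs, p$basis, params, seed = 30 + i,
                           compact = TRUE)
    res <- run_cq_analysis(ds, "within")
    errs <- vapply(seq_along(ds$results), function(t)
      temporal_error(ds$results[[t]],
                     ds$sequences[[ds$trials$sequence_id[t]]])$abs_pct,
      numeric(1))
    list(d = res$aggregate, err = mean(errs, na.rm = TRUE),
         trial_d = res$per_trial$d, trial_err = errs[res$per_trial$trial])
  })
  d <- vapply(subj, `[[`, numeric(1), "d")
  err <- vapply(subj, `[[`, numeric(1), "err")
  link <- cq_behavior_link(d, err,
                           trial_d = lapply(subj, `[[`, "trial_d"),
                           trial_err = lapply(subj, `[[`, "trial_err"))
  expect_lt(link$across$r, 0)
  expect_gt(link$split$mean_accurate, link$split$mean_inaccurate)
  expect_equal(nrow(link$per_subject), 6L)
  expect_error(cq_behavior_link(rep(1, 4), rep(2, 4)), "zero-variance")
})

test_that("trial-level link is null when timing noise is independent of d", {
  ds <- test_session("cq-on", n_blocks = 2, reps = 4, seed = 44,
                     params = test_params(finger_swap_prob = 0))
  res <- run_cq_analysis(ds, "within")
  errs <- vapply(res$per_trial$trial, function(t)
    temporal_error(ds$results[[t]],
                   ds$sequences[[ds$trials$sequence_id[t]]])$abs_pct,
    numeric(1))
  ct <- correlate(res$per_trial$d, errs)
  expect_lt(abs(ct$r), 2.6 / sqrt(length(errs)))
})
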