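test_that("window means reduce each half-open window to its channel mean", {
  const <- fake_epoch(matrix(3.5, 4, 200), t0 = 101)
  wf <- extract_window_means(const, window_grid(-100, 90, 10))
  expect_true(all(wf$X == 3.5))

  ramp <- fake_epoch(matrix(rep(0:199, each = 2), 2, 200, byrow = FALSE),
                     t0 = 1)
  # signal = sample index starting at 0: window [0, 10) averages 0..9
  wf <- extract_window_means(ramp, window_grid(0, 10, 10))
  expect_equal(as.numeric(wf$X[1, ]), c(4.5, 4.5))

  set.seed(1)
  ep <- fake_epoch(matrix(rnorm(6 * 300), 6, 300), t0 = 151)
  grid <- window_grid(-150, 140, 10)
  wf <- extract_window_means(ep, grid)
  for (j in seq_along(grid$starts)) {     # brute-force loop oracle
    cols <- (grid$starts[j] + 150):(grid$starts[j] + 159) + 1
    expect_equal(as.numeric(wf$X[j, ]), rowMeans(ep$data[, cols]),
                 tolerance = 1e-12)
  }
  expect_error(extract_window_means(ep, window_grid(-200, 0, 10)), "bounds")
})

test_that("training sets count presses per label scheme and match truth", {
  s <- default_sequences()["F1T1"]
  sch <- schedule_session(3, 4, s, seed = 2)
  b <- make_pattern_basis(16, seed = 1)
  params <- test_params(noise_sd = 0, timing_noise_sd = 0,
                        finger_swap_prob = 0)
  ds <- simulate_session(sch, s, b, params, seed = 2, compact = TRUE)
  tr <- build_training_set(ds, "press_position")
  expect_equal(dim(tr$X), c(60L, 16L))
  expect_true(all(table(tr$y) == 12L))
  iv <- build_training_set(ds, "preceding_interval")
  expect_equal(nrow(iv$X), 48L)
  expect_true(all(tr$position[tr$y == 3] == 3))
  # noiseless rows equal the composite patterns times the envelope factor
  env <- press_envelope_factor()
  truth <- composite_patterns(b, s$F1T1)
  for (k in 1:5) {
    rows <- tr$X[tr$y == k, , drop = FALSE]
    expect_equal(rows[1, ], truth[k, ] * env, tolerance = 1e-9)
  }
  ds$trials$correct_fingers <- FALSE
  expect_error(build_training_set(ds), "no correct trials")
})

test_that("gaussian-linear fit matches the pooled-shrinkage formula", {
  set.seed(4)
  X <- matrix(rnorm(60), 20, 3)
  y <- rep(1:4, each = 5)
  m <- fit_gaussian_linear(X, y, lambda = 0.1)
  mu <- t(sapply(1:4, function(k) colMeans(X[y == k, ])))
  resid <- X - mu[y, ]
  S <- crossprod(resid) / (20 - 4)
  cov_oracle <- 0.9 * S + 0.1 * mean(diag(S)) * diag(3)
  expect_equal(m$means, mu, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(m$cov, cov_oracle, tolerance = 1e-10)

  full <- fit_gaussian_linear(X, y, lambda = 1)
  expect_equal(full$cov, mean(diag(S)) * diag(3), tolerance = 1e-12)

  two <- fit_gaussian_linear(rbind(c(1, 0), c(0, 1)), 1:2, lambda = 1)
  expect_equal(two$means, rbind(c(1, 0), c(0, 1)), ignore_attr = TRUE)

  # more channels than rows: singular at lambda = 0
  Xs <- matrix(rnorm(40), 4, 10)
  expect_error(fit_gaussian_linear(Xs, c(1, 1, 2, 2), lambda = 0),
               "singular")
})

test_that("posteriors equal the explicit Gaussian-density Bayes oracle", {
  set.seed(7)
  for (rep in 1:25) {
    C <- sample(2:6, 1)
    X <- matrix(rnorm(40 * C), 40, C)
    y <- rep(1:5, 8)
    m <- fit_gaussian_linear(X, y, lambda = runif(1, 0.05, 0.9))
    x <- rnorm(C)
    dens <- vapply(1:5, function(k) {
      d <- x - m$means[k, ]
      exp(-0.5 * as.numeric(d %*% solve(m$cov, d))) /
        sqrt((2 * pi)^C * det(m$cov))
    }, numeric(1))
    expect_equal(posterior(m, x), dens / sum(dens), tolerance = 1e-12)
  }
})

test_that("posterior symmetries hold: chance, invariance, permutation", {
  set.seed(8)
  X <- matrix(rnorm(100), 25, 4)
  y <- rep(1:5, 5)
  m <- fit_gaussian_linear(X, y, lambda = 0.2)
  x <- rnorm(4)

  same <- m
  same$means <- matrix(1, 5, 4)
  expect_equal(posterior(same, x), rep(0.2, 5))

  sep <- m
  sep$means <- diag(5)[, 1:4] * 50
  expect_equal(which.max(posterior(sep, sep$means[3, ])), 3L)
  expect_gt(posterior(sep, sep$means[3, ])[3], 0.999)

  # translation invariance
  shift <- m
  shift$means <- sweep(m$means, 2, rep(2.5, 4), `+`)
  expect_equal(posterior(shift, x + 2.5), posterior(m, x), tolerance = 1e-12)

  # scale invariance with covariance scaled by c^2
  cc <- 3
  scaled <- fit_gaussian_linear(X * cc, y, lambda = 0.2)
  expect_equal(posterior(scaled, x * cc), posterior(m, x), tolerance = 1e-10)

  # label permutation permutes posteriors
  perm <- c(3, 1, 4, 5, 2)
  mp <- fit_gaussian_linear(X, perm[y], lambda = 0.2)
  expect_equal(posterior(mp, x)[perm], posterior(m, x), tolerance = 1e-12)
})

test_that("full shrinkage reduces the rule to nearest class mean", {
  set.seed(9)
  X <- matrix(rnorm(60), 15, 4) + rep(1:3, each = 5)
  y <- rep(1:3, each = 5)
  m <- fit_gaussian_linear(X, y, lambda = 1)
  for (i in 1:20) {
    x <- rnorm(4, sd = 2)
    d2 <- colSums((t(m$means) - x)^2)
    expect_equal(which.max(posterior(m, x)), which.min(d2))
  }
})

test_that("decoded traces are normalized and peak at the right presses", {
  s <- default_sequences()["F1T1"]
  sch <- schedule_session(2, 3, s, seed = 3)
  b <- make_pattern_basis(16, seed = 2)
  params <- test_params(noise_sd = 0, timing_noise_sd = 0,
                        finger_swap_prob = 0)
  ds <- simulate_session(sch, s, b, params, seed = 3)
  tr <- build_training_set(ds)
  model <- fit_gaussian_linear(tr$X, tr$y, lambda = 0.5)
  ep <- ds$epochs[[1]]
  grid <- window_grid(-1000, 5000, 10)
  trace <- decode_trace(model, ep, grid)
  expect_equal(colSums(trace$probs), rep(1, ncol(trace$probs)),
               tolerance = 1e-12)
  for (k in 1:5) {
    w <- max(which(trace$window_starts <= ep$events$presses[k] - 10))
    expect_equal(unname(which.max(trace$probs[, w])), k)
  }
})

test_that("cross-validation never tests a trial on its own model", {
  s <- default_sequences()
  sch <- schedule_session(1, 10, s["F1T1"], seed = 4)
  b <- make_pattern_basis(16, seed = 3)
  params <- test_params(noise_sd = 0, timing_noise_sd = 0,
                        finger_swap_prob = 0)
  ds <- simulate_session(sch, s["F1T1"], b, params, seed = 4, compact = TRUE)
  cv <- crossval_decode(ds, k_folds = 10, seed = 5)
  expect_true(all(table(cv$fold) == 1L))           # leave-one-out here
  expect_equal(cv$accuracy, rep(1, 5))             # separable, noiseless

  noisy <- test_session(n_blocks = 2, reps = 4, seed = 6,
                        params = test_params())
  noisy$basis <- NULL
  cv2 <- crossval_decode(noisy, k_folds = 4, seed = 6)
  expect_true(all(cv2$accuracy > 0.5))
  expect_error(crossval_decode(noisy, k_folds = 100), "too few")
})

test_that("chance-level data decodes at one in five", {
  s <- default_sequences()
  sch <- schedule_session(2, 6, s, seed = 7)
  params <- test_params(finger_swap_prob = 0)
  ds <- simulate_session(sch, s, zero_basis(16), params, seed = 7,
                         compact = TRUE)
  cv <- crossval_decode(ds, k_folds = 4, seed = 8)
  acc <- mean(cv$accuracy)
  n <- sum(ds$trials$correct_fingers) * 5
  expect_lt(abs(acc - 0.2), 2.6 * sqrt(0.2 * 0.8 / n))
})

test_that("boxcar smoothing is a truncated centered moving average", {
  p <- c(0.4, 0.25, 0.2, 0.1, 0.05)
  tr <- constant_trace(p)
  expect_equal(smooth_trace(tr, 100)$probs, tr$probs)

  imp <- probability_trace(rbind(c(rep(0, 20), 1, rep(0, 19)),
                                 matrix(1 / 4, 4, 40)),
                           seq(-200, by = 10, length.out = 40), 10)
  sm <- smooth_trace(imp, 100)
  expect_equal(sum(sm$probs[1, ] == 0.1), 10L)
  expect_equal(sum(sm$probs[1, ]), 1)

  set.seed(10)
  rnd <- probability_trace(matrix(runif(5 * 30), 5, 30),
                           seq(0, by = 10, length.out = 30), 10)
  sm <- smooth_trace(rnd, 50)
  for (j in 1:30) {                      # loop oracle, width 5 bins
    lo <- max(1, j - 2); hi <- min(30, j + 2)
    expect_equal(sm$probs[, j], rowMeans(rnd$probs[, lo:hi, drop = FALSE]),
                 tolerance = 1e-12)
  }
  expect_error(smooth_trace(rnd, 5), "multiple")
})
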