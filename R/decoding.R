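# Window-mean feature extraction and the Gaussian-linear (LDA) multiclass
# classifier producing per-window posterior probabilities for the five
# press classes.

#' Define a non-overlapping window grid
#'
#' Windows are half-open `[t, t + width)` in ms relative to the go cue,
#' contiguous on the grid.
#'
#' @param start,end Grid extent (ms); windows cover `[start, end)`.
#' @param width Window width in ms (default 10; 5/20/50 are the supported
#'   alternatives for window-size control analyses).
#' @return List with `starts` and `width`.
#' @export
window_grid <- function(start = -2000, end = 8500, width = 10) {
  if (end - start < width) stop("grid shorter than one window")
  list(starts = seq(start, end - width, by = width), width = width)
}

#' Extract per-window channel means from an epoch
#'
#' Each feature row is the per-channel mean amplitude over one half-open
#' window. No filtering or baseline correction is applied.
#'
#' @param epoch An `"epoch_recording"`.
#' @param grid A [window_grid()].
#' @return An object of class `"window_features"`: `X` (windows x channels),
#'   `window_starts`, `width`.
#' @export
extract_window_means <- function(epoch, grid) {
  fs <- epoch$fs
  w <- round(grid$width * fs / 1000)
  i0 <- .sample_index(grid$starts, epoch$t0, fs)
  if (any(i0 < 1L) || any(i0 + w - 1L > ncol(epoch$data)))
    stop("window grid exceeds epoch bounds")
  X <- t(vapply(seq_along(i0), function(j)
    rowMeans(epoch$data[, i0[j]:(i0[j] + w - 1L), drop = FALSE]),
    numeric(nrow(epoch$data))))
  structure(list(X = X, window_starts = grid$starts, width = grid$width),
            class = "window_features")
}

#' Press-onset training features of one trial
#'
#' Per press, the mean over the half-open `delta`-ms window ending at the
#' recorded press onset, `[onset - delta, onset)` -- the signal immediately
#' before the registered response.
#'
#' @param epoch An `"epoch_recording"`.
#' @param delta Window width in ms.
#' @return 5 x channels matrix.
#' @export
press_window_features <- function(epoch, delta = 10) {
  fs <- epoch$fs
  w <- round(delta * fs / 1000)
  t(vapply(epoch$events$presses, function(tp) {
    hi <- .sample_index(tp, epoch$t0, fs) - 1L
    lo <- hi - w + 1L
    if (lo < 1L || hi > ncol(epoch$data))
      stop("press window exceeds epoch bounds")
    rowMeans(epoch$data[, lo:hi, drop = FALSE])
  }, numeric(nrow(epoch$data))))
}

# Resolve press features / grid features for a dataset regardless of storage.
.dataset_press_features <- function(dataset, delta = 10) {
  if (!is.null(dataset$features)) {
    if (dataset$features$delta != delta)
      stop("compact dataset stores delta = ", dataset$features$delta)
    return(dataset$features$press_X)
  }
  n <- nrow(dataset$trials)
  out <- array(NA_real_, c(n, 5, dataset$n_channels))
  for (i in seq_len(n))
    out[i, , ] <- press_window_features(dataset$epochs[[i]], delta)
  out
}

.dataset_grid_features <- function(dataset, grid = NULL) {
  if (!is.null(dataset$features)) {
    f <- dataset$features
    if (!is.null(grid) &&
        !(all(grid$starts %in% f$window_starts) && grid$width == f$width))
      stop("requested grid not covered by compact dataset features")
    keep <- if (is.null(grid)) seq_along(f$window_starts) else
      match(grid$starts, f$window_starts)
    return(list(X = f$grid_X[, keep, , drop = FALSE],
                window_starts = f$window_starts[keep], width = f$width))
  }
  if (is.null(grid)) grid <- window_grid(-2000, 0, 10)
  n <- nrow(dataset$trials)
  X <- array(NA_real_, c(n, length(grid$starts), dataset$n_channels))
  for (i in seq_len(n))
    X[i, , ] <- extract_window_means(dataset$epochs[[i]], grid)$X
  list(X = X, window_starts = grid$starts, width = grid$width)
}

#' Assemble a training set from a dataset
#'
#' One row per press per correct-finger trial: the `delta`-ms window mean
#' ending at that press onset. Labels follow the chosen scheme: ordinal press
#' position (1-5), finger identity, or the class of the preceding target
#' interval (press 1 has no preceding interval and is excluded under that
#' scheme).
#'
#' @param dataset A `"cq_dataset"`.
#' @param label_scheme One of `"press_position"`, `"finger_identity"`,
#'   `"preceding_interval"`.
#' @param delta Training-window width (ms).
#' @return List with `X` (rows x channels), `y` (integer labels), `trial`
#'   (source trial index) and `position` (press position of each row).
#' @export
build_training_set <- function(dataset,
                               label_scheme = c("press_position",
                                                "finger_identity",
                                                "preceding_interval"),
                               delta = 10) {
  label_scheme <- match.arg(label_scheme)
  keep <- which(dataset$trials$correct_fingers)
  if (!length(keep)) stop("no correct trials to train on")
  press_X <- .dataset_press_features(dataset, delta)
  positions <- if (label_scheme == "preceding_interval") 2:5 else 1:5
  rows <- expand.grid(k = positions, i = keep)
  X <- matrix(NA_real_, nrow(rows), dataset$n_channels)
  y <- integer(nrow(rows))
  for (r in seq_len(nrow(rows))) {
    i <- rows$i[r]; k <- rows$k[r]
    spec <- dataset$sequences[[dataset$trials$sequence_id[i]]]
    X[r, ] <- press_X[i, k, ]
    y[r] <- switch(label_scheme,
                   press_position = k,
                   finger_identity = spec$finger_order[k],
                   preceding_interval = match(spec$interval_order[k],
                                              cq_target_intervals))
  }
  list(X = X, y = y, trial = rows$i, position = rows$k,
       label_scheme = label_scheme)
}

#' Fit the Gaussian-linear classifier
#'
#' Class means are per-class row means; the common covariance is the pooled
#' (class-demeaned) channel covariance of all training rows, regularized by
#' shrinkage toward a scaled identity:
#' `(1 - lambda) * S + lambda * mean(diag(S)) * I`. Priors are uniform unless
#' given.
#'
#' @param X Rows x channels training matrix.
#' @param y Class labels (one per row).
#' @param lambda Shrinkage weight in `[0, 1]`. With many channels and few
#'   training rows the raw pooled covariance is singular, so `lambda > 0` is
#'   required in practice.
#' @param priors Optional class prior probabilities (default uniform).
#' @return An object of class `"gaussian_linear"` with `means` (K x channels),
#'   `cov`, its Cholesky factor, `lambda`, `priors` and `classes`.
#' @export
fit_gaussian_linear <- function(X, y, lambda = 0.1, priors = NULL) {
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  X <- as.matrix(X)
  classes <- sort(unique(y))
  K <- length(classes)
  means <- t(vapply(classes, function(cl)
    colMeans(X[y == cl, , drop = FALSE]), numeric(ncol(X))))
  resid <- X - means[match(y, classes), , drop = FALSE]
  dof <- nrow(X) - K
  S <- if (dof > 0) crossprod(resid) / dof else
    matrix(0, ncol(X), ncol(X))
  target <- mean(diag(S))
  if (target == 0) target <- 1  # zero-residual training set: unit sphere
  cov <- (1 - lambda) * S + lambda * target * diag(ncol(X))
  R <- tryCatch(chol(cov), error = function(e) NULL)
  if (is.null(R))
    stop("pooled covariance is singular; increase lambda above 0")
  if (is.null(priors)) priors <- rep(1 / K, K)
  if (abs(sum(priors) - 1) > 1e-8) stop("priors must sum to 1")
  structure(list(K = K, classes = classes, means = means, cov = cov,
                 chol = R, lambda = lambda, priors = priors),
            class = "gaussian_linear")
}

#' Posterior class probabilities
#'
#' `p_k` is proportional to `prior_k * N(x; mean_k, cov)`, computed in the log
#' domain with a log-sum-exp normalization so that the probabilities sum to 1
#' exactly.
#'
#' @param model A [fit_gaussian_linear()] model.
#' @param x A channel vector, or a matrix with one observation per row.
#' @return A probability vector of length K, or an n x K matrix.
#' @export
posterior <- function(model, x) {
  single <- is.null(dim(x))
  X <- if (single) matrix(x, 1) else as.matrix(x)
  if (!all(is.finite(X))) stop("observations must be finite")
  Rinv <- backsolve(model$chol, diag(ncol(X)))
  logp <- vapply(seq_len(model$K), function(k) {
    delta <- sweep(X, 2, model$means[k, ])
    -0.5 * rowSums((delta %*% Rinv)^2) + log(model$priors[k])
  }, numeric(nrow(X)))
  logp <- matrix(logp, nrow(X), model$K)
  m <- apply(logp, 1, max)
  p <- exp(logp - m)
  p <- p / rowSums(p)
  if (single) p[1, ] else p
}

#' Decode a posterior-probability trace for one epoch
#'
#' @param model A fitted [fit_gaussian_linear()] model.
#' @param epoch An `"epoch_recording"`.
#' @param grid A [window_grid()].
#' @return An object of class `"probability_trace"`: `probs` (K x windows,
#'   columns summing to 1), `window_starts`, `width`.
#' @export
decode_trace <- function(model, epoch, grid) {
  wf <- extract_window_means(epoch, grid)
  probability_trace(t(posterior(model, wf$X)), wf$window_starts, wf$width,
                    sequence_id = epoch$sequence_id)
}

#' Construct a probability trace object
#' @param probs K x windows matrix of posteriors (columns sum to 1).
#' @param window_starts Window start times (ms, go-cue clock).
#' @param width Window width (ms).
#' @param sequence_id Optional metadata.
#' @export
probability_trace <- function(probs, window_starts, width = 10,
                              sequence_id = NA_character_) {
  probs <- as.matrix(probs)
  if (ncol(probs) != length(window_starts))
    stop("probs columns must match window_starts")
  structure(list(probs = probs, window_starts = window_starts,
                 width = width, sequence_id = sequence_id),
            class = "probability_trace")
}

#' Cross-validated decoding of a dataset
#'
#' Seeded fold assignment stratified by sequence; every trial's press-window
#' posteriors (and, optionally, its preparation-grid trace) are computed from
#' a model never trained on that trial. Training is within sequence, on
#' correct trials only, with press-position labels.
#'
#' @param dataset A `"cq_dataset"`.
#' @param k_folds Number of folds (>= 2; trials per sequence must be >= folds).
#' @param delta Training-window width (ms).
#' @param grid Optional [window_grid()]; if given, held-out traces over the
#'   grid are returned.
#' @param lambda Shrinkage for [fit_gaussian_linear()].
#' @param seed Seed for the fold assignment.
#' @return List with `press_prob` (trials x 5 posterior of the true press),
#'   `press_pred` (trials x 5 argmax class), `accuracy` (per-press fraction of
#'   held-out windows whose argmax equals the true press), `fold`, and
#'   `traces` (list of `"probability_trace"` or NULL). Rows for
#'   incorrect-finger trials are NA.
#' @export
crossval_decode <- function(dataset, k_folds = 10, delta = 10, grid = NULL,
                            lambda = 0.1, seed = 1) {
  if (k_folds < 2L) stop("k_folds must be >= 2")
  tab <- dataset$trials
  press_X <- .dataset_press_features(dataset, delta)
  gridf <- if (!is.null(grid)) .dataset_grid_features(dataset, grid) else NULL
  n <- nrow(tab)
  fold <- rep(NA_integer_, n)
  set.seed(seed)
  for (sid in unique(tab$sequence_id)) {
    idx <- which(tab$sequence_id == sid & tab$correct_fingers)
    if (length(idx) < k_folds)
      stop("too few correct trials in sequence ", sid, " for ", k_folds,
           " folds")
    fold[idx] <- sample(rep_len(seq_len(k_folds), length(idx)))
  }
  press_prob <- matrix(NA_real_, n, 5)
  press_pred <- matrix(NA_integer_, n, 5)
  traces <- if (!is.null(gridf)) vector("list", n) else NULL
  for (sid in unique(tab$sequence_id)) {
    sidx <- which(tab$sequence_id == sid & tab$correct_fingers)
    for (f in seq_len(k_folds)) {
      test <- sidx[fold[sidx] == f]
      train <- sidx[fold[sidx] != f]
      if (!length(test)) next
      Xtr <- do.call(rbind, lapply(train, function(i) press_X[i, , ]))
      ytr <- rep(1:5, times = length(train))
      model <- fit_gaussian_linear(Xtr, ytr, lambda)
      for (i in test) {
        p <- posterior(model, press_X[i, , ])
        press_prob[i, ] <- p[cbind(1:5, 1:5)]
        press_pred[i, ] <- apply(p, 1, which.max)
        if (!is.null(gridf))
          traces[[i]] <- probability_trace(
            t(posterior(model, gridf$X[i, , ])),
            gridf$window_starts, gridf$width, sequence_id = sid)
      }
    }
  }
  ok <- which(tab$correct_fingers)
  accuracy <- vapply(1:5, function(k)
    mean(press_pred[ok, k] == k), numeric(1))
  list(press_prob = press_prob, press_pred = press_pred,
       accuracy = accuracy, fold = fold, traces = traces)
}

#' Boxcar-smooth a probability trace (display only)
#'
#' Centered moving average per press row with truncated windows at the edges.
#' Smoothing is for display; all statistics are computed on unsmoothed traces.
#'
#' @param trace A `"probability_trace"`.
#' @param width Boxcar width in ms; must be a multiple of the trace's window
#'   width.
#' @return A smoothed `"probability_trace"`.
#' @export
smooth_trace <- function(trace, width = 100) {
  b <- width / trace$width
  if (width < trace$width || b != round(b))
    stop("width must be a multiple of the trace window width")
  b <- as.integer(b)
  left <- (b - 1L) %/% 2L
  right <- b - 1L - left
  W <- ncol(trace$probs)
  sm <- trace$probs
  for (j in seq_len(W)) {
    lo <- max(1L, j - left); hi <- min(W, j + right)
    sm[, j] <- rowMeans(trace$probs[, lo:hi, drop = FALSE])
  }
  probability_trace(sm, trace$window_starts, trace$width, trace$sequence_id)
}
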