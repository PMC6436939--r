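# Channel-space searchlight mapping of CQ distance and production decoding
# accuracy: small channel neighborhoods as features, per-channel statistics,
# z-scored maps and group t-maps.

#' Regular grid sensor layout for synthetic channels
#'
#' Channels are placed row-major on a square grid with unit spacing. Any
#' real layout can be supplied instead as a data.frame with columns
#' `channel`, `x`, `y`.
#'
#' @param n_channels Number of channels.
#' @param spacing Grid spacing (arbitrary units).
#' @return data.frame with `channel`, `x`, `y`.
#' @export
grid_layout <- function(n_channels, spacing = 1) {
  side <- ceiling(sqrt(n_channels))
  i <- seq_len(n_channels) - 1L
  data.frame(channel = seq_len(n_channels),
             x = (i %% side) * spacing,
             y = (i %/% side) * spacing)
}

#' Searchlight membership: each channel plus its k nearest neighbors
#'
#' Euclidean nearest neighbors on the layout plane; distance ties are broken
#' by channel id order. The default `k = 2` gives 3-channel searchlights.
#'
#' @param layout Layout data.frame (`channel`, `x`, `y`).
#' @param k Number of neighbors (>= 0).
#' @return List (one per channel) of sorted channel-index vectors of length
#'   `k + 1` including the center channel.
#' @export
neighbors <- function(layout, k = 2) {
  n <- nrow(layout)
  if (n < k + 1L) stop("need at least k + 1 channels")
  if (anyDuplicated(layout[, c("x", "y")]))
    stop("duplicate channel positions in layout")
  D <- as.matrix(stats::dist(layout[, c("x", "y")]))
  lapply(seq_len(n), function(i) {
    if (k == 0L) return(i)
    ord <- order(D[i, ], seq_len(n))  # ties by channel id
    nb <- setdiff(ord, i)[seq_len(k)]
    sort(c(i, nb))
  })
}

.zscore_pop <- function(v) {
  s <- sqrt(mean((v - mean(v))^2))
  if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
}

# Fit with automatic shrinkage fallback for degenerate searchlight covariance.
.fit_gl_fallback <- function(X, y, lambda) {
  for (lam in unique(c(lambda, 0.5, 1))) {
    m <- tryCatch(fit_gaussian_linear(X, y, lam), error = function(e) NULL)
    if (!is.null(m)) return(m)
  }
  stop("could not fit searchlight classifier at any shrinkage level")
}

#' Searchlight map of CQ distance at a fixed preparation probe
#'
#' Per channel: train the classifier on that searchlight's press-onset
#' features (correct trials, within sequence), decode a single 10-ms window at
#' `t_probe` before the go cue in each trial, and compute the per-trial CQ
#' distance (presses 1-5). Per-channel value = median across trials within
#' sequence, then mean across sequences; finally z-scored across channels
#' (population SD).
#'
#' @param dataset A `"cq_dataset"` (compact features must cover `t_probe`).
#' @param layout Sensor layout data.frame.
#' @param t_probe Start (ms) of the probe window, default -500.
#' @param k Neighbors per searchlight.
#' @param lambda Classifier shrinkage.
#' @param delta Training-window width (ms).
#' @return An object of class `"searchlight_map"`: data.frame with `channel`,
#'   `value`, `z`; attribute `kind = "cq_distance"`.
#' @export
searchlight_cq <- function(dataset, layout, t_probe = -500, k = 2,
                           lambda = 0.1, delta = 10) {
  nb <- neighbors(layout, k)
  press_X <- .dataset_press_features(dataset, delta)
  gridf <- .dataset_grid_features(dataset)
  probe_col <- match(t_probe, gridf$window_starts)
  if (is.na(probe_col)) stop("probe window not on the stored grid")
  tab <- dataset$trials
  seq_ids <- unique(tab$sequence_id)
  value <- vapply(seq_len(nrow(layout)), function(ch) {
    cols <- nb[[ch]]
    per_seq <- vapply(seq_ids, function(sid) {
      idx <- which(tab$sequence_id == sid & tab$correct_fingers)
      Xtr <- do.call(rbind, lapply(idx, function(i) press_X[i, , cols]))
      model <- .fit_gl_fallback(Xtr, rep(1:5, length(idx)), lambda)
      probe <- gridf$X[idx, probe_col, cols, drop = FALSE]
      p <- posterior(model, matrix(probe, length(idx), length(cols)))
      d <- rowMeans(p[, 1:4, drop = FALSE] - p[, 2:5, drop = FALSE])
      stats::median(d)
    }, numeric(1))
    mean(per_seq)
  }, numeric(1))
  out <- data.frame(channel = layout$channel, value = value,
                    z = .zscore_pop(value))
  attr(out, "kind") <- "cq_distance"
  class(out) <- c("searchlight_map", "data.frame")
  out
}

#' Searchlight map of production decoding accuracy
#'
#' Per channel: k-fold cross-validated press decoding accuracy on the
#' searchlight's press-onset features, within sequence, averaged across
#' presses and sequences; z-scored across channels.
#'
#' @inheritParams searchlight_cq
#' @param k_folds Cross-validation folds.
#' @param seed Seed for fold assignment.
#' @return A `"searchlight_map"` with attribute `kind = "decode_accuracy"`.
#' @export
searchlight_accuracy <- function(dataset, layout, k_folds = 5, k = 2,
                                 lambda = 0.1, delta = 10, seed = 1) {
  nb <- neighbors(layout, k)
  press_X <- .dataset_press_features(dataset, delta)
  tab <- dataset$trials
  seq_ids <- unique(tab$sequence_id)
  set.seed(seed)
  folds <- lapply(seq_ids, function(sid) {
    idx <- which(tab$sequence_id == sid & tab$correct_fingers)
    list(idx = idx, fold = sample(rep_len(seq_len(k_folds), length(idx))))
  })
  names(folds) <- seq_ids
  value <- vapply(seq_len(nrow(layout)), function(ch) {
    cols <- nb[[ch]]
    per_seq <- vapply(seq_ids, function(sid) {
      fi <- folds[[sid]]
      correct <- 0L; total <- 0L
      for (f in seq_len(k_folds)) {
        test <- fi$idx[fi$fold == f]
        train <- fi$idx[fi$fold != f]
        if (!length(test) || !length(train)) next
        Xtr <- do.call(rbind, lapply(train, function(i) press_X[i, , cols]))
        model <- .fit_gl_fallback(Xtr, rep(1:5, length(train)), lambda)
        for (i in test) {
          p <- posterior(model, press_X[i, , cols])
          correct <- correct + sum(apply(p, 1, which.max) == 1:5)
          total <- total + 5L
        }
      }
      correct / total
    }, numeric(1))
    mean(per_seq)
  }, numeric(1))
  out <- data.frame(channel = layout$channel, value = value,
                    z = .zscore_pop(value))
  attr(out, "kind") <- "decode_accuracy"
  class(out) <- c("searchlight_map", "data.frame")
  out
}

#' Group t-map over per-subject searchlight maps
#'
#' One-sample t statistic of the z values at each channel across subjects,
#' one-sided (greater than 0) per the directional CQ hypothesis. Channels
#' with zero variance across subjects get an infinite-t sentinel
#' (`degenerate = TRUE`) and are excluded from the significance mask.
#'
#' @param maps List of `"searchlight_map"`s (or a subjects x channels matrix
#'   of z values) over a common layout.
#' @param alpha Uncorrected significance level (default 0.01, the sensor-level
#'   display threshold).
#' @return data.frame with `channel`, `t`, `p`, `significant`, `degenerate`.
#' @export
group_tmap <- function(maps, alpha = 0.01) {
  Z <- if (is.matrix(maps)) maps else {
    chans <- lapply(maps, function(m) m$channel)
    if (length(unique(chans)) != 1L) stop("maps have mismatched layouts")
    do.call(rbind, lapply(maps, function(m) m$z))
  }
  n <- nrow(Z)
  if (n < 3L) stop("need >= 3 subjects")
  m <- colMeans(Z)
  s <- apply(Z, 2, stats::sd)
  degen <- s == 0
  tstat <- ifelse(degen, sign(m) * Inf, m / (s / sqrt(n)))
  p <- ifelse(degen, NA_real_, stats::pt(tstat, n - 1, lower.tail = FALSE))
  data.frame(channel = seq_len(ncol(Z)), t = tstat, p = p,
             significant = !degen & !is.na(p) & p < alpha,
             degenerate = degen)
}
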