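# The competitive-queuing network: a temporal context layer associated with
# items by Hebbian learning, a parallel planning layer whose graded
# activations queue the upcoming items, and a competitive choice layer with
# winner-take-all selection and self-inhibition of produced items.

#' Temporal context layer states
#'
#' Three standard context forms. `decaying_start`: each state mixes a start
#' axis (weight `decay^(t-1)`) with a position-unique axis, so overlap with
#' the first state decays over positions. `start_end`: states mix a decaying
#' start-anchored component `decay^(t-1)` and a growing end-anchored component
#' `decay^(n-t)`. `overlapping_states`: Gaussian bumps of width `sigma_c` over
#' a continuous position axis (sampled densely), so overlap between positions
#' i and j falls off as `exp(-(i-j)^2 / (4 sigma_c^2))`. All states are
#' unit-norm and nonnegative.
#'
#' @param form One of `"decaying_start"`, `"start_end"`,
#'   `"overlapping_states"`.
#' @param n_steps Sequence length.
#' @param params List of form parameters: `decay` (default 0.75) for the first
#'   two forms, `sigma_c` (default 1) for overlapping states.
#' @return An object of class `"context_layer"` with `states`
#'   (n_steps x dims), `form`, `n_steps`, `params`.
#' @export
context_states <- function(form = c("decaying_start", "start_end",
                                    "overlapping_states"),
                           n_steps, params = list()) {
  form <- match.arg(form)
  if (n_steps < 1L) stop("n_steps must be >= 1")
  states <- switch(form,
    decaying_start = {
      decay <- params$decay %||% 0.75
      if (decay <= 0 || decay >= 1) stop("decay must be in (0, 1)")
      t(vapply(seq_len(n_steps), function(t) {
        v <- numeric(n_steps + 1L)
        w <- decay^(t - 1)
        v[1] <- w
        v[t + 1L] <- 1 - w
        v / sqrt(sum(v^2))
      }, numeric(n_steps + 1L)))
    },
    start_end = {
      decay <- params$decay %||% 0.75
      if (decay <= 0 || decay >= 1) stop("decay must be in (0, 1)")
      t(vapply(seq_len(n_steps), function(t) {
        v <- c(decay^(t - 1), decay^(n_steps - t))
        v / sqrt(sum(v^2))
      }, numeric(2L)))
    },
    overlapping_states = {
      sigma <- params$sigma_c %||% 1
      if (sigma <= 0) stop("sigma_c must be positive")
      x <- seq(1 - 6 * sigma, n_steps + 6 * sigma, by = sigma / 50)
      t(vapply(seq_len(n_steps), function(t) {
        v <- exp(-(x - t)^2 / (2 * sigma^2))
        v / sqrt(sum(v^2))
      }, numeric(length(x))))
    })
  structure(list(form = form, n_steps = as.integer(n_steps),
                 params = params, states = states),
            class = "context_layer")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Create an empty CQ network
#'
#' @param context A [context_states()] layer.
#' @param K Number of item nodes.
#' @param inhibition_factor Residual planning input of produced items: 0
#'   (default) removes them from the competition entirely; a value in (0, 1)
#'   gives graded self-inhibition.
#' @return An object of class `"cq_network"` with zero association weights.
#' @export
cq_network <- function(context, K, inhibition_factor = 0) {
  if (inhibition_factor < 0 || inhibition_factor >= 1)
    stop("inhibition_factor must be in [0, 1)")
  structure(list(W = matrix(0, ncol(context$states), K),
                 K = as.integer(K), context = context,
                 inhibition_factor = inhibition_factor,
                 inhibited = rep(FALSE, K), items = NULL),
            class = "cq_network")
}

#' Hebbian encoding of an item sequence
#'
#' Accumulates the outer product of each context state with the one-hot item
#' vector: `W <- W + state_t o onehot(item_t)`. Inhibition flags are cleared.
#' Encoding is linear: encoding the same sequence twice doubles `W`.
#'
#' @param network A [cq_network()].
#' @param item_sequence Integer vector of distinct items in `1..K`, length
#'   `n_steps`.
#' @return The updated network (with `items` recording the encoded sequence).
#' @export
encode <- function(network, item_sequence) {
  ctx <- network$context
  if (length(item_sequence) != ctx$n_steps)
    stop("item_sequence length must equal the context's n_steps")
  if (anyDuplicated(item_sequence) || any(item_sequence < 1L) ||
      any(item_sequence > network$K))
    stop("items must be distinct and in 1..K")
  for (t in seq_len(ctx$n_steps))
    network$W[, item_sequence[t]] <- network$W[, item_sequence[t]] +
      ctx$states[t, ]
  network$inhibited <- rep(FALSE, network$K)
  network$items <- as.integer(item_sequence)
  network
}

#' Planning-layer activations for one context state
#' @param network An encoded [cq_network()].
#' @param t Position whose context state to reinstate.
#' @return Numeric vector of K planning activations `W' state_t`.
#' @export
planning_activations <- function(network, t) {
  as.numeric(crossprod(network$W, network$context$states[t, ]))
}

#' Recall a sequence from the network
#'
#' Context states are replayed exactly as during encoding. At each step the
#' planning layer activates all items (`W' state_t`), produced items'
#' planning input is suppressed, i.i.d. Gaussian noise of SD `sigma_n` is
#' added at the choice layer, and the most active item wins (exact ties to
#' the lowest index), is emitted, and is self-inhibited.
#'
#' @param network An encoded [cq_network()].
#' @param sigma_n Choice-layer noise SD.
#' @param seed Optional seed.
#' @return List with `order` (produced items), `activations` (K x n_steps
#'   planning activations before suppression) and `suppressed` (K x n_steps
#'   logical, items out of the competition at each step).
#' @export
recall <- function(network, sigma_n = 0, seed = NULL) {
  if (is.null(network$items)) stop("network has not encoded a sequence")
  if (!is.null(seed)) set.seed(seed)
  n <- network$context$n_steps
  suppressed <- network$inhibited
  produced <- integer(n)
  acts <- matrix(NA_real_, network$K, n)
  supp_hist <- matrix(NA, network$K, n)
  gamma <- network$inhibition_factor
  for (t in seq_len(n)) {
    a <- planning_activations(network, t)
    acts[, t] <- a
    supp_hist[, t] <- suppressed
    choice <- a
    if (gamma == 0) choice[suppressed] <- -Inf
    else choice[suppressed] <- gamma * choice[suppressed]
    if (all(choice == -Inf))
      stop("empty competition: all items are suppressed")
    if (sigma_n > 0) {
      eps <- stats::rnorm(network$K, 0, sigma_n)
      choice[is.finite(choice)] <- choice[is.finite(choice)] +
        eps[is.finite(choice)]
    }
    winner <- which.max(choice)
    produced[t] <- winner
    suppressed[winner] <- TRUE
  }
  list(order = produced, activations = acts, suppressed = supp_hist)
}

#' Monte-Carlo error profile of the CQ network
#'
#' Repeated noisy recall of the encoded sequence. Reports the error rate
#' (fraction of trials with any out-of-order item), the histogram of absolute
#' transposition distances `|produced position - encoded position|` over
#' misplaced items, and the gradient separation: the mean difference between
#' consecutive items' planning activations at the first recall step -- the
#' model-level analogue of the decoder's CQ distance.
#'
#' @param network An encoded [cq_network()].
#' @param sigma_n Choice-layer noise SD.
#' @param n_trials Number of Monte-Carlo trials.
#' @param seed Seed.
#' @return List with `error_rate`, `transposition_hist` (named counts over
#'   distances 1..n-1), `gradient_separation`, `n_trials`.
#' @export
error_profile <- function(network, sigma_n, n_trials, seed = 1) {
  if (n_trials < 1L) stop("n_trials must be >= 1")
  items <- network$items
  n <- length(items)
  set.seed(seed)
  n_err <- 0L
  disp <- integer(0)
  for (b in seq_len(n_trials)) {
    out <- recall(network, sigma_n)$order
    if (!identical(out, items)) {
      n_err <- n_err + 1L
      pos_true <- match(items, items)        # 1..n
      pos_prod <- match(items, out)          # produced position of each item
      dd <- abs(pos_prod - pos_true)
      disp <- c(disp, dd[dd > 0])
    }
  }
  a1 <- planning_activations(network, 1L)[items]
  hist <- tabulate(disp, nbins = n - 1L)
  names(hist) <- as.character(seq_len(n - 1L))
  list(error_rate = n_err / n_trials,
       transposition_hist = hist,
       gradient_separation = mean(a1[-n] - a1[-1]),
       n_trials = n_trials)
}
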