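# Quality-aware client weighting: per-client metrics (convergence velocity,
# training stability, confidence-based reliability) are z-scored across
# clients, combined with positive gamma coefficients, and passed through a
# softmax to give aggregation weights on the probability simplex.

#' Weighting configuration
#'
#' @param gamma1,gamma2,gamma3 Strictly positive coefficients for the
#'   velocity, inverse-stability, and reliability terms of the composite
#'   score.
#' @param epsilon_stability Small constant guarding the `1/s_k` term when a
#'   loss trajectory has zero variance.
#' @param min_history_rounds Minimum loss-history length before the
#'   quality-aware weights replace size-proportional ones (velocity and
#'   stability are undefined with fewer than 2 observations).
#' @param confidence_mode `"max-probability"` (confidence of a sample is the
#'   maximum predicted class probability) or `"evidential"` (confidence
#'   `1 - K / S` from a non-negative evidence head with Dirichlet strength
#'   `S`).
#' @return Object of class `weighting_config`.
#' @export
weighting_config <- function(gamma1 = 1, gamma2 = 1, gamma3 = 1,
                             epsilon_stability = 1e-8,
                             min_history_rounds = 2L,
                             confidence_mode = "max-probability") {
  if (any(c(gamma1, gamma2, gamma3) <= 0))
    stop("all gamma coefficients must be strictly positive")
  stopifnot(epsilon_stability > 0, min_history_rounds >= 2)
  if (!confidence_mode %in% c("max-probability", "evidential"))
    stop("unknown confidence_mode: ", confidence_mode)
  structure(list(gamma1 = gamma1, gamma2 = gamma2, gamma3 = gamma3,
                 epsilon_stability = epsilon_stability,
                 min_history_rounds = as.integer(min_history_rounds),
                 confidence_mode = confidence_mode),
            class = "weighting_config")
}

#' Convergence velocity of a loss trajectory
#'
#' Absolute change of the local loss between the first and last recorded
#' round, divided by the number of rounds:
#' `c_k = |L_k(w_T) - L_k(w_0)| / T`.
#'
#' @param loss_history Numeric vector of losses at rounds `0 .. T`.
#' @param T Number of rounds spanned (default `length(loss_history) - 1`).
#' @return Non-negative scalar.
#' @export
convergence_velocity <- function(loss_history, T = length(loss_history) - 1L) {
  if (T < 1) stop("T must be >= 1")
  if (length(loss_history) < 2 || anyNA(loss_history[c(1, length(loss_history))]))
    stop("loss history must contain both endpoints")
  abs(loss_history[length(loss_history)] - loss_history[1]) / T
}

#' Training stability of a loss trajectory
#'
#' Population variance (divisor = number of observations) of the recorded
#' local losses. Low variance indicates a smooth, internally consistent
#' optimization; its reciprocal rewards stable clients in the composite
#' score.
#'
#' @param loss_history Numeric vector with at least 2 entries.
#' @return Non-negative scalar.
#' @export
training_stability <- function(loss_history) {
  n <- length(loss_history)
  if (n < 2) stop("insufficient loss history: need at least 2 entries")
  m <- mean(loss_history)
  sum((loss_history - m)^2) / n
}

#' Data reliability from per-sample confidences
#'
#' Arithmetic mean of the per-sample prediction confidences, each in
#' `[0, 1]`.
#'
#' @param confidences Non-empty numeric vector in `[0, 1]`.
#' @return Scalar in `[0, 1]`.
#' @export
data_reliability <- function(confidences) {
  if (length(confidences) == 0) stop("confidences must be non-empty")
  if (any(confidences < 0 | confidences > 1))
    stop("confidences must lie in [0, 1]")
  mean(confidences)
}

#' Evidential confidence from non-negative evidence
#'
#' For a sample with evidence vector `e >= 0` over `K` classes, the
#' Dirichlet strength is `S = K + sum(e)` and the confidence is
#' `1 - K / S`, in `[0, 1)`.
#'
#' @param evidence Matrix (samples x classes) of non-negative evidence.
#' @return Vector of per-sample confidences.
#' @export
evidential_confidence <- function(evidence) {
  if (any(evidence < 0)) stop("evidence must be non-negative")
  K <- ncol(evidence)
  S <- K + rowSums(evidence)
  1 - K / S
}

# z-score a metric across clients with population sigma; a degenerate
# (constant) metric contributes 0 for every client.
zscore_pop <- function(x) {
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  if (s == 0) rep(0, length(x)) else (x - mu) / s
}

#' Composite client scores
#'
#' Each of `c_k`, `1/(s_k + eps)`, and `q_k` is z-scored independently
#' across clients (population standard deviation; a metric with zero spread
#' normalizes to 0 for everyone), then combined as
#' `gamma1 * c_hat + gamma2 * invs_hat + gamma3 * q_hat`.
#'
#' @param metrics Data frame (or list of lists) with per-client `c`
#'   (velocity), `s` (stability), `q` (reliability).
#' @param cfg A [weighting_config()].
#' @return Numeric vector of normalized composite scores, one per client.
#' @export
composite_scores <- function(metrics, cfg = weighting_config()) {
  if (!inherits(cfg, "weighting_config")) stop("cfg must be a weighting_config")
  if (is.data.frame(metrics)) {
    cv <- metrics$c; sv <- metrics$s; qv <- metrics$q
  } else {
    cv <- vapply(metrics, `[[`, numeric(1), "c")
    sv <- vapply(metrics, `[[`, numeric(1), "s")
    qv <- vapply(metrics, `[[`, numeric(1), "q")
  }
  if (length(cv) < 1) stop("need at least one client")
  if (any(!is.finite(cv)) || any(!is.finite(sv))) stop("metrics must be finite")
  if (any(qv < 0 | qv > 1)) stop("reliability must lie in [0, 1]")
  inv_s <- 1 / (sv + cfg$epsilon_stability)
  cfg$gamma1 * zscore_pop(cv) + cfg$gamma2 * zscore_pop(inv_s) +
    cfg$gamma3 * zscore_pop(qv)
}

#' Softmax aggregation weights
#'
#' `alpha_k = exp(score_k) / sum_j exp(score_j)`, computed with
#' max-subtraction for overflow safety. All weights are strictly positive
#' and sum to 1.
#'
#' @param scores Finite numeric vector of client scores.
#' @return Numeric weight vector on the probability simplex.
#' @export
softmax_weights <- function(scores) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  e <- exp(scores - max(scores))
  e / sum(e)
}

#' Quality-weighted aggregation
#'
#' Computes per-client metrics from the recorded loss histories and
#' confidences, turns them into softmax weights, and aggregates
#' `w_{t+1} = sum_k alpha_k w_t^k`. Until every participating client has at
#' least `cfg$min_history_rounds` loss observations, size-proportional
#' FedAvg weights are used instead (cold start).
#'
#' @param params_list List of client parameter lists (post local training),
#'   one per participating client.
#' @param records List of client records for the same clients, each with
#'   `loss_history` and `confidence_mean`.
#' @param cfg A [weighting_config()].
#' @param round Current communication round index; when given, it is the
#'   divisor T of every client's convergence velocity (all clients are
#'   normalized by the same elapsed rounds, so sparse participation does
#'   not inflate the metric). Defaults to each client's own history span.
#' @param sizes Client sample counts (used for the cold-start fallback).
#' @param all_records Optional list of records for the full client
#'   population. When supplied, the z-score statistics are computed over
#'   every client with sufficient history (the population the metrics are
#'   defined over), and the softmax is
#'   renormalized over the round's participants; with only two
#'   participants, pairwise z-scores alone would quantize to +-1 and
#'   discard the metric magnitudes.
#' @return List with `params` (aggregated) and `weights` (the alpha vector
#'   actually used).
#' @export
aggregate_fl_lsnet <- function(params_list, records, cfg = weighting_config(),
                               round = NULL, sizes = NULL,
                               all_records = NULL) {
  K <- length(params_list)
  stopifnot(K == length(records))
  hist_len <- vapply(records, function(r) length(r$loss_history), integer(1))
  if (any(hist_len < cfg$min_history_rounds)) {
    if (is.null(sizes)) sizes <- rep(1, K)
    w <- sizes / sum(sizes)
    return(list(params = weighted_param_sum(params_list, w), weights = w))
  }
  if (is.null(all_records)) all_records <- records
  pool <- Filter(function(r)
    length(r$loss_history) >= cfg$min_history_rounds, all_records)
  met <- data.frame(
    c = vapply(pool, function(r) convergence_velocity(
      r$loss_history,
      T = if (is.null(round)) length(r$loss_history) - 1L else round),
      numeric(1)),
    s = vapply(pool, function(r) training_stability(r$loss_history),
               numeric(1)),
    q = vapply(pool, function(r) {
      q <- r$confidence_mean
      if (is.na(q)) 1 else q
    }, numeric(1)))
  scores <- composite_scores(met, cfg)
  ids_pool <- vapply(pool, function(r) r$client_id %||% NA_integer_,
                     numeric(1))
  ids_part <- vapply(records, function(r) r$client_id %||% NA_integer_,
                     numeric(1))
  pick <- if (anyNA(ids_pool) || anyNA(ids_part)) seq_len(K)
          else match(ids_part, ids_pool)
  alpha <- softmax_weights(scores[pick])
  list(params = weighted_param_sum(params_list, alpha), weights = alpha)
}

#' Specification for the linear convergence bound
#'
#' @param mu Strong-convexity constant (> 0).
#' @param L Smoothness constant (>= mu).
#' @param learning_rate Step size, required in `(0, 2/L)` for the bound to
#'   apply.
#' @param initial_gap Initial optimality gap `L(w_0) - L(w*)`.
#' @return Object of class `convergence_bound_spec`.
#' @export
convergence_bound_spec <- function(mu, L, learning_rate, initial_gap) {
  stopifnot(mu > 0, L >= mu, learning_rate > 0, initial_gap >= 0)
  structure(list(mu = mu, L = L, learning_rate = learning_rate,
                 initial_gap = initial_gap),
            class = "convergence_bound_spec")
}

#' Linear convergence bound for strongly convex objectives
#'
#' Returns the bound `(1 - eta * mu)^(t + 1) * initial_gap` on the expected
#' optimality gap after round `t`. Warns when `eta * mu >= 1` or
#' `eta >= 2/L`, where the stated contraction regime does not hold.
#'
#' @param spec A [convergence_bound_spec()].
#' @param t Round index (>= 0); may be a vector.
#' @return Bound value(s), strictly decreasing in `t` when
#'   `0 < eta * mu < 1`.
#' @export
convergence_bound <- function(spec, t) {
  stopifnot(inherits(spec, "convergence_bound_spec"), all(t >= 0))
  em <- spec$learning_rate * spec$mu
  if (em >= 1)
    warning("eta * mu >= 1: the bound is vacuous (non-contractive)")
  if (spec$learning_rate >= 2 / spec$L)
    warning("learning rate outside the stated regime (0, 2/L)")
  (1 - em)^(t + 1) * spec$initial_gap
}
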