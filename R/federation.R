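#' Federated experiment configuration
#'
#' Defaults follow the reference training recipe: batch size 8, learning
#' rate 0.01, weight decay 5e-5, Adam, 3 clients, 70 rounds, one local
#' epoch, participation ratio 0.8.
#'
#' @param num_clients Number of clients K (>= 1).
#' @param rounds Communication rounds T (>= 1).
#' @param local_epochs Local epochs E per round (>= 0).
#' @param participation_ratio Fraction C of clients sampled per round, in
#'   (0, 1].
#' @param learning_rate Local step size.
#' @param optimizer `"adam"`, `"sgd"`, or `"gd"` (plain gradient descent,
#'   used where the linear convergence theory applies).
#' @param batch_size Mini-batch size; `Inf` for full-batch.
#' @param weight_decay Decoupled weight decay coefficient.
#' @param fedprox_mu Proximal coefficient for FedProx (>= 0).
#' @param strategy Aggregation strategy: `"fedavg"`, `"fedprox"`, or
#'   `"fl-lsnet"` (quality-aware softmax weighting).
#' @param seed Integer master seed; every random choice in a run derives
#'   from it.
#' @return An object of class `fl_config`.
#' @export
fl_config <- function(num_clients = 3L, rounds = 70L, local_epochs = 1L,
                      participation_ratio = 0.8, learning_rate = 0.01,
                      optimizer = "adam", batch_size = 8L,
                      weight_decay = 5e-5, fedprox_mu = 0.01,
                      strategy = "fedavg", seed = 1L) {
  stopifnot(num_clients >= 1, rounds >= 1, local_epochs >= 0,
            participation_ratio > 0, participation_ratio <= 1,
            learning_rate > 0, fedprox_mu >= 0)
  if (!strategy %in% c("fedavg", "fedprox", "fl-lsnet"))
    stop("unknown strategy: ", strategy)
  structure(list(num_clients = as.integer(num_clients),
                 rounds = as.integer(rounds),
                 local_epochs = as.integer(local_epochs),
                 participation_ratio = participation_ratio,
                 learning_rate = learning_rate, optimizer = optimizer,
                 batch_size = batch_size, weight_decay = weight_decay,
                 fedprox_mu = fedprox_mu, strategy = strategy,
                 seed = as.integer(seed)),
            class = "fl_config")
}

#' Size-weighted federated averaging
#'
#' Coordinate-wise weighted mean of client parameters with weights
#' `p_k = n_k / sum(n_j)`. Permutation invariant; the output lies inside the
#' per-coordinate envelope of the inputs.
#'
#' @param params_list List of shape-compatible parameter lists.
#' @param sizes Positive client sample counts `n_k`.
#' @return Aggregated parameter list.
#' @export
fedavg_aggregate <- function(params_list, sizes) {
  stopifnot(length(params_list) >= 1, length(sizes) == length(params_list))
  if (any(sizes <= 0) || sum(sizes) <= 0) stop("sizes must be positive")
  weighted_param_sum(params_list, sizes / sum(sizes))
}

# Sum_k w_k * params_k with shape checking.
weighted_param_sum <- function(params_list, weights) {
  weights <- unname(as.numeric(weights))
  ref <- params_list[[1]]
  nm <- names(ref)
  for (pl in params_list[-1]) {
    if (!identical(names(pl), nm)) stop("client parameter names differ")
    for (n in nm)
      if (!identical(dim(pl[[n]]), dim(ref[[n]])) ||
          length(pl[[n]]) != length(ref[[n]]))
        stop("shape mismatch in parameter ", n)
  }
  out <- lapply(ref, function(p) p * weights[1])
  if (length(params_list) > 1L)
    for (k in 2:length(params_list))
      for (n in nm) out[[n]] <- out[[n]] + weights[k] * params_list[[k]][[n]]
  out
}

#' Sample participating clients for a round
#'
#' Draws `max(1, round-half-up(C * K))` distinct client ids uniformly
#' without replacement, reproducibly from `(seed, round)`.
#'
#' @param K Number of clients.
#' @param C Participation ratio in (0, 1].
#' @param round Round index.
#' @param seed Master seed.
#' @return Sorted integer vector of client ids.
#' @export
sample_participants <- function(K, C, round, seed) {
  if (K < 1) stop("K must be >= 1")
  stopifnot(C > 0, C <= 1)
  m <- max(1L, as.integer(round_half_up(C * K)))
  sort(with_seed(derive_seed(seed, 3301L, round), sample.int(K, m)))
}

#' Run a federated training simulation
#'
#' Executes `fl$rounds` rounds of broadcast, local training, and
#' aggregation. `"fedavg"` and `"fedprox"` aggregate with size weights
#' `p_k`; `"fl-lsnet"` derives softmax weights from per-client convergence
#' velocity, stability, and confidence-based reliability (falling back to
#' `p_k` until enough loss history exists). The entire run is reproducible
#' from `fl$seed`.
#'
#' @param fl An [fl_config()].
#' @param model An [fl_model()].
#' @param data Dataset object shared by all shards.
#' @param shards List of `fl$num_clients` non-empty integer index vectors.
#' @param strategy Overrides `fl$strategy` when given.
#' @param weighting A [weighting_config()] (used by `"fl-lsnet"`).
#' @param eval_data,eval_idx Optional held-out dataset and indices; when the
#'   model predicts probabilities, per-round global accuracy is logged.
#' @param val_fraction Fraction of each shard held out locally for the
#'   confidence (reliability) estimate.
#' @return Object of class `fl_history`: list with `rounds` (one log per
#'   round: round index, participants, per-client initial losses,
#'   aggregation weights, metrics), `final_params`, `records`, `config`.
#' @export
run_federated <- function(fl, model, data, shards, strategy = fl$strategy,
                          weighting = weighting_config(),
                          eval_data = NULL, eval_idx = NULL,
                          val_fraction = 0.1) {
  K <- fl$num_clients
  if (length(shards) != K) stop("need exactly one shard per client")
  if (any(vapply(shards, length, integer(1)) == 0L))
    stop("every client needs a non-empty shard")
  n_k <- vapply(shards, length, integer(1))
  # local train/validation split (validation feeds the reliability metric)
  val_idx <- vector("list", K)
  train_idx <- vector("list", K)
  for (k in seq_len(K)) {
    nv <- if (val_fraction <= 0) 0L else max(1L, floor(val_fraction * n_k[k]))
    if (nv == 0L || nv >= n_k[k]) {
      val_idx[[k]] <- shards[[k]]
      train_idx[[k]] <- shards[[k]]
    } else {
      pick <- with_seed(derive_seed(fl$seed, 9103L, k),
                        sample(seq_along(shards[[k]]), nv))
      val_idx[[k]] <- shards[[k]][pick]
      train_idx[[k]] <- shards[[k]][-pick]
    }
  }
  records <- lapply(seq_len(K), function(k)
    list(client_id = k, n_k = n_k[k], loss_history = numeric(0),
         confidence_mean = NA_real_))
  global <- model$init(fl$seed)
  # server-side parameter store: each client's most recent upload (the
  # quality-aware strategy aggregates this set, so clients skipping a round
  # still contribute their last update)
  stored <- vector("list", K)
  logs <- vector("list", fl$rounds)
  for (t in seq_len(fl$rounds)) {
    parts <- sample_participants(K, fl$participation_ratio, t, fl$seed)
    params_list <- vector("list", length(parts))
    init_losses <- numeric(length(parts))
    for (ii in seq_along(parts)) {
      k <- parts[ii]
      res <- local_train(model, data, train_idx[[k]], global, fl,
                         seed = derive_seed(fl$seed, 5501L, t, k),
                         strategy = strategy)
      params_list[[ii]] <- res$params
      init_losses[ii] <- res$initial_loss
      records[[k]]$loss_history <- c(records[[k]]$loss_history,
                                     res$initial_loss)
      # reliability input: confidence of the broadcast global model on the
      # client's local validation split (a locally overfit model would rate
      # its own shard too confidently)
      if (!is.null(model$predict_proba)) {
        pr <- model$predict_proba(global, data, val_idx[[k]])
        records[[k]]$confidence_mean <- mean(apply(pr, 1, max))
      } else records[[k]]$confidence_mean <- 1
    }
    if (strategy == "fl-lsnet") {
      for (ii in seq_along(parts)) stored[[parts[ii]]] <- params_list[[ii]]
      have <- which(!vapply(stored, is.null, logical(1)))
      ag <- aggregate_fl_lsnet(stored[have], records[have], weighting,
                               sizes = n_k[have], all_records = records)
      global <- ag$params
      weights <- ag$weights
      names(weights) <- paste0("client", have)
    } else {
      global <- fedavg_aggregate(params_list, n_k[parts])
      weights <- n_k[parts] / sum(n_k[parts])
      names(weights) <- paste0("client", parts)
    }
    mean_loss <- sum(init_losses * n_k[parts]) / sum(n_k[parts])
    if (!is.finite(mean_loss))
      stop("federated run diverged (non-finite global loss) at round ", t)
    metrics <- list(mean_loss = mean_loss)
    if (!is.null(eval_data) && !is.null(model$predict_proba)) {
      if (is.null(eval_idx)) eval_idx <- seq_along(eval_data$y)
      pr <- model$predict_proba(global, eval_data, eval_idx)
      pred <- max.col(pr, ties.method = "first") - 1L
      metrics$accuracy <- 100 * mean(pred == eval_data$y[eval_idx])
    }
    logs[[t]] <- list(round = t, participants = parts,
                      local_losses = init_losses, weights = weights,
                      metrics = metrics)
  }
  structure(list(rounds = logs, final_params = global, records = records,
                 config = fl, strategy = strategy),
            class = "fl_history")
}

#' Centralized training reference
#'
#' Repeats [local_train()] from the current parameters for `rounds`
#' iterations on a single dataset, using the same per-round seed derivation
#' as a single-client federated run; with `K = 1, C = 1` the two
#' trajectories coincide exactly.
#'
#' @inheritParams run_federated
#' @param idx Indices of the training subset.
#' @param rounds Number of outer iterations.
#' @return List with `params` and `loss` (initial loss per round).
#' @export
train_centralized <- function(fl, model, data, idx, rounds = fl$rounds) {
  params <- model$init(fl$seed)
  losses <- numeric(rounds)
  for (t in seq_len(rounds)) {
    res <- local_train(model, data, idx, params, fl,
                       seed = derive_seed(fl$seed, 5501L, t, 1L),
                       strategy = "fedavg")
    params <- res$params
    losses[t] <- res$initial_loss
  }
  list(params = params, loss = losses)
}

#' Per-round summary of a federated run
#'
#' @param history An `fl_history`.
#' @return Data frame with round, mean loss, accuracy (if logged), and one
#'   weight column per client (NA when not participating).
#' @export
summarize_history <- function(history) {
  K <- history$config$num_clients
  rows <- lapply(history$rounds, function(lg) {
    w <- rep(NA_real_, K)
    w[as.integer(sub("client", "", names(lg$weights)))] <- lg$weights
    df <- data.frame(round = lg$round, mean_loss = lg$metrics$mean_loss,
                     accuracy = lg$metrics$accuracy %||% NA_real_)
    wdf <- as.data.frame(as.list(stats::setNames(w, paste0("w_client", 1:K))))
    cbind(df, wdf)
  })
  do.call(rbind, rows)
}
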