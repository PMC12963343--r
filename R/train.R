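# Trainable-model interface and local optimizers.
#
# A "federated model" is a small closure bundle so the federation loop can
# drive either the image backbone or analytic toy objectives (used to verify
# the optimization machinery against closed forms):
#   init(seed)                    -> named parameter list
#   loss_grad(params, data, idx)  -> list(loss, grads)
#   eval_loss(params, data, idx)  -> scalar loss (no gradients)
#   predict_proba(params, data, idx) -> matrix (n x classes), or NULL

#' Construct a federated-model interface
#'
#' @param init Function `(seed) -> params` (named list of numeric arrays).
#' @param loss_grad Function `(params, data, idx) -> list(loss, grads)`.
#' @param eval_loss Optional function `(params, data, idx) -> loss`; defaults
#'   to calling `loss_grad` and discarding gradients.
#' @param predict_proba Optional function `(params, data, idx)` returning a
#'   row-stochastic matrix of class probabilities.
#' @return An object of class `fl_model`.
#' @export
fl_model <- function(init, loss_grad, eval_loss = NULL, predict_proba = NULL) {
  if (is.null(eval_loss))
    eval_loss <- function(params, data, idx) loss_grad(params, data, idx)$loss
  structure(list(init = init, loss_grad = loss_grad, eval_loss = eval_loss,
                 predict_proba = predict_proba), class = "fl_model")
}

#' LS-network federated model
#'
#' Wraps the image backbone as an [fl_model()]. `data` must be a list with
#' `x` (array `(n, H, W, 3)`, pixel values in `[0, 1]`) and `y` (integer
#' labels in `0 .. num_classes - 1`).
#'
#' @param cfg An `lsnet_config`.
#' @param max_batch Forward-pass batch size used for prediction.
#' @return An `fl_model`.
#' @export
lsnet_fl_model <- function(cfg, max_batch = 32L) {
  force(cfg)
  fl_model(
    init = function(seed) build_lsnet(cfg, seed)$params,
    loss_grad = function(params, data, idx) {
      r <- lsnet_loss_grad_at(cfg, params,
                              data$x[idx, , , , drop = FALSE],
                              data$y[idx] + 1L)
      list(loss = r$loss, grads = r$grads)
    },
    eval_loss = function(params, data, idx) {
      tot <- 0
      for (ch in split(idx, ceiling(seq_along(idx) / max_batch))) {
        z <- net_forward(cfg, params, data$x[ch, , , , drop = FALSE])$logits
        p <- softmax_rows(z)
        tot <- tot + sum(-log(pmax(p[cbind(seq_along(ch), data$y[ch] + 1L)],
                                   1e-12)))
      }
      tot / length(idx)
    },
    predict_proba = function(params, data, idx) {
      out <- matrix(NA_real_, length(idx), cfg$num_classes)
      pos <- 0L
      for (ch in split(idx, ceiling(seq_along(idx) / max_batch))) {
        z <- net_forward(cfg, params, data$x[ch, , , , drop = FALSE])$logits
        out[pos + seq_along(ch), ] <- softmax_rows(z)
        pos <- pos + length(ch)
      }
      out
    })
}

#' Quadratic toy federated model
#'
#' Each sample is a pair `(a, b)` contributing loss `a/2 * (w - b)^2` to the
#' scalar parameter `w`. The global optimum under size weights has the
#' closed form `sum(p_k E_k[a b]) / sum(p_k E_k[a])`, which makes this model
#' the reference for verifying the federated averaging loop.
#'
#' @param w0 Initial parameter value.
#' @return An `fl_model` whose `data` is a data frame with columns `a`, `b`.
#' @export
quadratic_fl_model <- function(w0 = 0) {
  force(w0)
  fl_model(
    init = function(seed) list(w = w0),
    loss_grad = function(params, data, idx) {
      a <- data$a[idx]; b <- data$b[idx]
      list(loss = mean(0.5 * a * (params$w - b)^2),
           grads = list(w = mean(a * (params$w - b))))
    })
}

# ---- optimizers ----------------------------------------------------------

opt_init <- function(params, fl) {
  st <- list(t = 0L)
  if (fl$optimizer == "adam") {
    st$m <- lapply(params, function(p) p * 0)
    st$v <- lapply(params, function(p) p * 0)
  }
  st
}

# One update step. Weight decay is decoupled (applied directly to the
# weights, not through the gradient moments), and skipped when zero.
opt_step <- function(state, params, grads, fl) {
  lr <- fl$learning_rate
  wd <- fl$weight_decay
  state$t <- state$t + 1L
  if (fl$optimizer %in% c("sgd", "gd")) {
    for (n in names(grads)) {
      params[[n]] <- params[[n]] - lr * grads[[n]]
      if (wd > 0) params[[n]] <- params[[n]] - lr * wd * params[[n]]
    }
  } else if (fl$optimizer == "adam") {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    bc1 <- 1 - b1^state$t
    bc2 <- 1 - b2^state$t
    for (n in names(grads)) {
      state$m[[n]] <- b1 * state$m[[n]] + (1 - b1) * grads[[n]]
      state$v[[n]] <- b2 * state$v[[n]] + (1 - b2) * grads[[n]]^2
      step <- (state$m[[n]] / bc1) / (sqrt(state$v[[n]] / bc2) + eps)
      if (wd > 0) step <- step + wd * params[[n]]
      params[[n]] <- params[[n]] - lr * step
    }
  } else stop("unknown optimizer: ", fl$optimizer)
  list(state = state, params = params)
}

#' Local client training
#'
#' Runs `E = fl$local_epochs` epochs of mini-batch optimization starting
#' from the broadcast global parameters. With `strategy = "fedprox"` the
#' proximal penalty `mu/2 * ||w - w_global||^2` is added to every batch
#' objective. `E = 0` returns the global parameters unchanged.
#'
#' @param model An [fl_model()].
#' @param data The full dataset object the model understands.
#' @param idx Integer indices of this client's shard (non-empty).
#' @param global_params Broadcast global parameters.
#' @param fl An [fl_config()].
#' @param seed Seed controlling batch shuffling.
#' @param strategy `"fedavg"`, `"fedprox"`, or `"fl-lsnet"` (the proximal
#'   term is only active for `"fedprox"`).
#' @return List with `params` (updated), `loss_trace` (per-epoch mean batch
#'   loss), and `initial_loss` (loss of `global_params` on the shard).
#' @export
local_train <- function(model, data, idx, global_params, fl,
                        seed = fl$seed, strategy = fl$strategy) {
  if (length(idx) == 0L) stop("client shard is empty")
  initial_loss <- model$eval_loss(global_params, data, idx)
  if (!is.finite(initial_loss))
    stop("non-finite loss on client shard before training")
  if (fl$local_epochs == 0L)
    return(list(params = global_params, loss_trace = numeric(0),
                initial_loss = initial_loss))
  params <- global_params
  state <- opt_init(params, fl)
  bs <- fl$batch_size
  if (!is.finite(bs) || bs >= length(idx)) bs <- length(idx)
  mu <- if (identical(strategy, "fedprox")) fl$fedprox_mu else 0
  trace <- numeric(fl$local_epochs)
  for (e in seq_len(fl$local_epochs)) {
    ord <- with_seed(derive_seed(seed, 7001L, e),
                     if (length(idx) > 1L) sample(idx) else idx)
    batches <- split(ord, ceiling(seq_along(ord) / bs))
    bl <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      lg <- model$loss_grad(params, data, batches[[bi]])
      loss <- lg$loss
      grads <- lg$grads
      if (mu > 0) {
        for (n in names(grads)) {
          diff <- params[[n]] - global_params[[n]]
          grads[[n]] <- grads[[n]] + mu * diff
          loss <- loss + mu / 2 * sum(diff^2)
        }
      }
      if (!is.finite(loss))
        stop("non-finite local loss at epoch ", e, ", batch ", bi,
             "; aborting local training")
      res <- opt_step(state, params, grads, fl)
      state <- res$state
      params <- res$params
      bl[bi] <- loss
    }
    trace[e] <- mean(bl)
  }
  list(params = params, loss_trace = trace, initial_loss = initial_loss)
}
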