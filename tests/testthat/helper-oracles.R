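# Independent brute-force oracles and toy fixtures. Everything here loops
# over pixels explicitly and shares no code with the implementation.

# pointwise conv by explicit pixel loop
oracle_pointwise <- function(x, w, b) {
  d <- dim(x)
  out <- array(0, dim = c(d[1], d[2], d[3], ncol(w)))
  for (n in seq_len(d[1])) for (i in seq_len(d[2])) for (j in seq_len(d[3]))
    out[n, i, j, ] <- as.vector(x[n, i, j, ] %*% w) + b
  out
}

# depthwise KxK conv, zero padding, by explicit loop
oracle_depthwise <- function(x, k, b) {
  d <- dim(x)
  K <- dim(k)[1]
  p <- (K - 1) %/% 2
  out <- array(0, dim = d)
  for (n in seq_len(d[1])) for (i in seq_len(d[2])) for (j in seq_len(d[3]))
    for (cc in seq_len(d[4])) {
      acc <- 0
      for (a in seq_len(K)) for (bb in seq_len(K)) {
        ii <- i + a - 1 - p; jj <- j + bb - 1 - p
        if (ii >= 1 && ii <= d[2] && jj >= 1 && jj <= d[3])
          acc <- acc + x[n, ii, jj, cc] * k[a, bb, cc]
      }
      out[n, i, j, cc] <- acc + b[cc]
    }
  out
}

# per-channel KxK box (mean) filter with zero padding
oracle_box_filter <- function(x, K) {
  k <- array(1 / K^2, dim = c(K, K, dim(x)[4]))
  oracle_depthwise(x, k, numeric(dim(x)[4]))
}

# grouped dynamic convolution by explicit loop; weight layout
# d = (g-1)*K^2 + j with j column-major in the K x K window
oracle_ska <- function(x, w, G, K) {
  d <- dim(x)
  cg <- d[4] / G
  p <- (K - 1) %/% 2
  out <- array(0, dim = d)
  for (n in seq_len(d[1])) for (i in seq_len(d[2])) for (j in seq_len(d[3]))
    for (cc in seq_len(d[4])) {
      g <- ceiling(cc / cg)
      ker <- matrix(w[n, i, j, ((g - 1) * K^2 + 1):(g * K^2)], K, K)
      acc <- 0
      for (a in seq_len(K)) for (bb in seq_len(K)) {
        ii <- i + a - 1 - p; jj <- j + bb - 1 - p
        if (ii >= 1 && ii <= d[2] && jj >= 1 && jj <= d[3])
          acc <- acc + x[n, ii, jj, cc] * ker[a, bb]
      }
      out[n, i, j, cc] <- acc
    }
  out
}

rand_fmap <- function(seed, B, H, W, C) {
  set.seed(seed)
  array(rnorm(B * H * W * C), dim = c(B, H, W, C))
}

micro_stage <- function() {
  list(out_channels = 8L, num_blocks = 1L, k_large = 7L, k_small = 3L,
       groups = 4L)
}

micro_block_params <- function(seed = 5) {
  fllsnet:::with_seed(seed, fllsnet:::init_lsnet_params(lsnet_micro_config()))
}

# multinomial logistic regression as an fl_model (data: list(x matrix, y 0-based))
logistic_fl_model <- function(d, K) {
  fl_model(
    init = function(seed) {
      set.seed(seed)
      list(W = matrix(rnorm(d * K, sd = 0.1), d, K), b = numeric(K))
    },
    loss_grad = function(params, data, idx) {
      X <- data$x[idx, , drop = FALSE]
      z <- X %*% params$W + rep(params$b, each = nrow(X))
      z <- z - apply(z, 1, max)
      p <- exp(z) / rowSums(exp(z))
      n <- nrow(X)
      pick <- cbind(seq_len(n), data$y[idx] + 1L)
      dz <- p
      dz[pick] <- dz[pick] - 1
      dz <- dz / n
      list(loss = -mean(log(pmax(p[pick], 1e-12))),
           grads = list(W = crossprod(X, dz), b = colSums(dz)))
    },
    predict_proba = function(params, data, idx) {
      X <- data$x[idx, , drop = FALSE]
      z <- X %*% params$W + rep(params$b, each = nrow(X))
      z <- z - apply(z, 1, max)
      exp(z) / rowSums(exp(z))
    })
}

quadratic_shards <- function(seed, n = c(30, 50, 20), centers = c(1, 3, 5)) {
  set.seed(seed)
  lab <- rep(seq_along(n), times = n)
  list(data = data.frame(a = runif(sum(n), 0.5, 2),
                         b = rnorm(sum(n), centers[lab], 0.2)),
       shards = split(seq_len(sum(n)), lab))
}
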