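# Low-level array operations for the network. All feature maps use a
# channels-last layout: dim(x) == c(batch, H, W, C). R arrays are
# column-major, so the batch index varies fastest and the channel index
# slowest; a per-channel vector v broadcasts over an array as
# rep(v, each = B*H*W).

zeros_like <- function(x) array(0, dim = dim(x))

#' @noRd
bcast_channel <- function(v, bhw) rep(v, each = bhw)

# Zero-pad the two spatial dimensions by p pixels on each side.
pad_hw <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, dim = c(d[1], d[2] + 2L * p, d[3] + 2L * p, d[4]))
  out[, (p + 1L):(p + d[2]), (p + 1L):(p + d[3]), ] <- x
  out
}

unpad_hw <- function(x, p, H, W) {
  if (p == 0L) return(x)
  x[, (p + 1L):(p + H), (p + 1L):(p + W), , drop = FALSE]
}

as_bhwc_matrix <- function(x) {
  d <- dim(x)
  matrix(x, nrow = d[1] * d[2] * d[3], ncol = d[4])
}

# ---- pointwise (1x1) convolution: a matrix multiply over channels --------

pw_forward <- function(x, w, b = NULL) {
  d <- dim(x)
  xm <- as_bhwc_matrix(x)
  ym <- xm %*% w
  if (!is.null(b)) ym <- ym + rep(b, each = nrow(ym))
  list(y = array(ym, dim = c(d[1], d[2], d[3], ncol(w))), xm = xm)
}

pw_backward <- function(dy, cache, w) {
  d <- dim(dy)
  dym <- as_bhwc_matrix(dy)
  dw <- crossprod(cache$xm, dym)
  db <- colSums(dym)
  dxm <- tcrossprod(dym, w)
  list(dx = array(dxm, dim = c(d[1], d[2], d[3], nrow(w))), dw = dw, db = db)
}

# ---- depthwise KxK convolution, stride 1, "same" zero padding ------------
# kernel k: array (K, K, C); optional bias b: length C

dw_forward <- function(x, k, b = NULL) {
  d <- dim(x)
  K <- dim(k)[1]
  p <- (K - 1L) %/% 2L
  xp <- pad_hw(x, p)
  bhw <- d[1] * d[2] * d[3]
  out <- array(0, dim = d)
  for (a in seq_len(K)) {
    for (bb in seq_len(K)) {
      sl <- xp[, a:(a + d[2] - 1L), bb:(bb + d[3] - 1L), , drop = FALSE]
      out <- out + sl * bcast_channel(k[a, bb, ], bhw)
    }
  }
  if (!is.null(b)) out <- out + bcast_channel(b, bhw)
  list(y = out, xp = xp)
}

dw_backward <- function(dy, cache, k) {
  d <- dim(dy)
  K <- dim(k)[1]
  p <- (K - 1L) %/% 2L
  bhw <- d[1] * d[2] * d[3]
  dxp <- zeros_like(cache$xp)
  dk <- zeros_like(k)
  for (a in seq_len(K)) {
    for (bb in seq_len(K)) {
      sl <- cache$xp[, a:(a + d[2] - 1L), bb:(bb + d[3] - 1L), , drop = FALSE]
      dk[a, bb, ] <- colSums(as_bhwc_matrix(dy * sl))
      dxp[, a:(a + d[2] - 1L), bb:(bb + d[3] - 1L), ] <-
        dxp[, a:(a + d[2] - 1L), bb:(bb + d[3] - 1L), , drop = FALSE] +
        dy * bcast_channel(k[a, bb, ], bhw)
    }
  }
  db <- colSums(as_bhwc_matrix(dy))
  list(dx = unpad_hw(dxp, p, d[2], d[3]), dk = dk, db = db)
}

# ---- full KxK convolution with stride s (used by the stem) ---------------
# weight w: array (K, K, Cin, Cout); bias b: length Cout

conv_forward <- function(x, w, b = NULL, stride = 1L, pad = NULL) {
  d <- dim(x)
  K <- dim(w)[1]
  if (is.null(pad)) pad <- (K - 1L) %/% 2L
  Ho <- (d[2] + 2L * pad - K) %/% stride + 1L
  Wo <- (d[3] + 2L * pad - K) %/% stride + 1L
  xp <- pad_hw(x, pad)
  cout <- dim(w)[4]
  ym <- matrix(0, d[1] * Ho * Wo, cout)
  slices <- vector("list", K * K)
  for (a in seq_len(K)) {
    for (bb in seq_len(K)) {
      sl <- xp[, seq.int(a, by = stride, length.out = Ho),
               seq.int(bb, by = stride, length.out = Wo), , drop = FALSE]
      slm <- as_bhwc_matrix(sl)
      slices[[(bb - 1L) * K + a]] <- slm
      ym <- ym + slm %*% matrix(w[a, bb, , ], nrow = d[4], ncol = cout)
    }
  }
  if (!is.null(b)) ym <- ym + rep(b, each = nrow(ym))
  list(y = array(ym, dim = c(d[1], Ho, Wo, cout)), slices = slices,
       in_dim = d, pad = pad, stride = stride, Ho = Ho, Wo = Wo)
}

conv_backward <- function(dy, cache, w) {
  d <- cache$in_dim
  K <- dim(w)[1]
  cout <- dim(w)[4]
  dym <- as_bhwc_matrix(dy)
  dw <- zeros_like(w)
  dxp <- array(0, dim = c(d[1], d[2] + 2L * cache$pad, d[3] + 2L * cache$pad, d[4]))
  for (a in seq_len(K)) {
    for (bb in seq_len(K)) {
      slm <- cache$slices[[(bb - 1L) * K + a]]
      dw[a, bb, , ] <- crossprod(slm, dym)
      dslm <- tcrossprod(dym, matrix(w[a, bb, , ], nrow = d[4], ncol = cout))
      ih <- seq.int(a, by = cache$stride, length.out = cache$Ho)
      iw <- seq.int(bb, by = cache$stride, length.out = cache$Wo)
      dxp[, ih, iw, ] <- dxp[, ih, iw, , drop = FALSE] +
        array(dslm, dim = c(d[1], cache$Ho, cache$Wo, d[4]))
    }
  }
  db <- colSums(dym)
  list(dx = unpad_hw(dxp, cache$pad, d[2], d[3]), dw = dw, db = db)
}

# ---- strided depthwise 3x3 (inter-stage downsampling) --------------------

dws_forward <- function(x, k, stride = 2L) {
  d <- dim(x)
  K <- dim(k)[1]
  p <- (K - 1L) %/% 2L
  Ho <- (d[2] + 2L * p - K) %/% stride + 1L
  Wo <- (d[3] + 2L * p - K) %/% stride + 1L
  xp <- pad_hw(x, p)
  bhw <- d[1] * Ho * Wo
  out <- array(0, dim = c(d[1], Ho, Wo, d[4]))
  for (a in seq_len(K)) {
    for (bb in seq_len(K)) {
      sl <- xp[, seq.int(a, by = stride, length.out = Ho),
               seq.int(bb, by = stride, length.out = Wo), , drop = FALSE]
      out <- out + sl * bcast_channel(k[a, bb, ], bhw)
    }
  }
  list(y = out, xp = xp, in_dim = d, Ho = Ho, Wo = Wo, pad = p, stride = stride)
}

dws_backward <- function(dy, cache, k) {
  d <- cache$in_dim
  K <- dim(k)[1]
  bhw <- d[1] * cache$Ho * cache$Wo
  dk <- zeros_like(k)
  dxp <- zeros_like(cache$xp)
  for (a in seq_len(K)) {
    for (bb in seq_len(K)) {
      ih <- seq.int(a, by = cache$stride, length.out = cache$Ho)
      iw <- seq.int(bb, by = cache$stride, length.out = cache$Wo)
      sl <- cache$xp[, ih, iw, , drop = FALSE]
      dk[a, bb, ] <- colSums(as_bhwc_matrix(dy * sl))
      dxp[, ih, iw, ] <- dxp[, ih, iw, , drop = FALSE] +
        dy * bcast_channel(k[a, bb, ], bhw)
    }
  }
  list(dx = unpad_hw(dxp, cache$pad, d[2], d[3]), dk = dk)
}

# ---- activations and normalization ---------------------------------------

gelu_forward <- function(x) list(y = x * pnorm(x), x = x)

gelu_backward <- function(dy, cache) {
  x <- cache$x
  dy * (pnorm(x) + x * dnorm(x))
}

# Channel-wise layer normalization at each spatial position (ConvNeXt-style).
ln_forward <- function(x, gamma, beta, eps = 1e-6) {
  d <- dim(x)
  n <- d[1] * d[2] * d[3]
  xm <- as_bhwc_matrix(x)
  mu <- rowMeans(xm)
  xc <- xm - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xh <- xc * inv
  ym <- xh * rep(gamma, each = n) + rep(beta, each = n)
  list(y = array(ym, dim = d), xh = xh, inv = inv, xc = xc)
}

ln_backward <- function(dy, cache, gamma) {
  d <- dim(dy)
  n <- d[1] * d[2] * d[3]
  C <- d[4]
  dym <- as_bhwc_matrix(dy)
  dgamma <- colSums(dym * cache$xh)
  dbeta <- colSums(dym)
  dxh <- dym * rep(gamma, each = n)
  inv <- cache$inv
  xc <- cache$xc
  dv <- rowSums(dxh * xc) * (-0.5) * inv^3
  dmu <- rowSums(dxh) * (-inv) + dv * rowMeans(-2 * xc)
  dxm <- dxh * inv + dv * (2 * xc / C) + dmu / C
  list(dx = array(dxm, dim = d), dgamma = dgamma, dbeta = dbeta)
}

# ---- global average pooling ----------------------------------------------

gap_forward <- function(x) {
  d <- dim(x)
  a <- array(x, dim = c(d[1], d[2] * d[3], d[4]))
  y <- colSums(aperm(a, c(2, 1, 3))) / (d[2] * d[3])
  list(y = y, in_dim = d)  # y: (batch, C)
}

gap_backward <- function(dy, cache) {
  d <- cache$in_dim
  hw <- d[2] * d[3]
  da <- aperm(array(dy / hw, dim = c(d[1], d[4], hw)), c(1, 3, 2))
  array(da, dim = d)
}

dense_forward <- function(x, w, b) {
  list(y = x %*% w + rep(b, each = nrow(x)), x = x)
}

dense_backward <- function(dy, cache, w) {
  list(dx = tcrossprod(dy, w), dw = crossprod(cache$x, dy), db = colSums(dy))
}
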