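#' Configure an LS-convolution backbone
#'
#' Describes the staged encoder of the Large-Small Network: a stem of two
#' overlapping stride-2 convolutions, then a sequence of stages made of LS
#' blocks (large-kernel perception generating position-wise dynamic kernels,
#' consumed by small-kernel grouped aggregation), with stride-2 downsampling
#' between stages, and a global-average-pool + dense classification head.
#'
#' @param stem_channels Channel width of the first stem convolution.
#' @param stages List of per-stage settings; each element is a list with
#'   `out_channels`, `num_blocks`, `k_large` (odd, >= `k_small`), `k_small`
#'   (odd), and `groups` (must divide `out_channels`).
#' @param num_classes Number of output classes.
#' @param input_size Integer vector `c(H, W)`; must be divisible by the
#'   cumulative downsampling factor `4 * 2^(n_stages - 1)`.
#' @param activation Activation name; only `"gelu"` is implemented.
#' @param normalization `"layernorm"` (channel-wise at each position) or
#'   `"none"`.
#' @return An object of class `lsnet_config`.
#' @export
lsnet_config <- function(stem_channels, stages, num_classes,
                         input_size = c(224L, 224L),
                         activation = "gelu", normalization = "layernorm") {
  if (length(input_size) == 1L) input_size <- rep(input_size, 2L)
  stopifnot(stem_channels >= 1, num_classes >= 2, length(stages) >= 1)
  for (s in stages) {
    stopifnot(all(c("out_channels", "num_blocks", "k_large", "k_small",
                    "groups") %in% names(s)))
    if (s$k_large %% 2L == 0L)
      stop("k_large must be odd (even large kernels cannot preserve shape)")
    if (s$k_small %% 2L == 0L) stop("k_small must be odd")
    if (s$k_large < s$k_small) stop("k_large must be >= k_small")
    if (s$out_channels %% 2L != 0L)
      stop("out_channels must be even (LKP compresses channels to C/2)")
    if (s$out_channels %% s$groups != 0L)
      stop("groups must divide out_channels")
  }
  if (!activation %in% "gelu") stop("unsupported activation: ", activation)
  if (!normalization %in% c("layernorm", "none"))
    stop("unsupported normalization: ", normalization)
  down <- 4L * 2L^(length(stages) - 1L)
  if (any(input_size %% down != 0L))
    stop("input_size must be divisible by the cumulative downsampling (",
         down, ")")
  structure(list(stem_channels = as.integer(stem_channels),
                 stages = stages, num_classes = as.integer(num_classes),
                 input_size = as.integer(input_size),
                 activation = activation, normalization = normalization),
            class = "lsnet_config")
}

#' Default full-size backbone configuration
#'
#' Stage widths 96/192/384/768 with groups 4/8/16/32, 7x7 large kernels and
#' 3x3 small kernels at 224x224 input. Per-stage depths are set to
#' (1, 1, 2, 1); published parameter counts for this family are not
#' reproducible from the stage table alone, so depths are configurable.
#'
#' @param num_classes Number of classes (default 10).
#' @param depths Integer vector of per-stage block counts.
#' @return An `lsnet_config`.
#' @export
lsnet_table_config <- function(num_classes = 10L, depths = c(1L, 1L, 2L, 1L)) {
  ch <- c(96L, 192L, 384L, 768L)
  gr <- c(4L, 8L, 16L, 32L)
  stages <- lapply(1:4, function(i)
    list(out_channels = ch[i], num_blocks = as.integer(depths[i]),
         k_large = 7L, k_small = 3L, groups = gr[i]))
  lsnet_config(stem_channels = 48L, stages = stages,
               num_classes = num_classes, input_size = c(224L, 224L))
}

#' Micro backbone for desk-scale experiments
#'
#' Two stages of widths 8/16 at 32x32 input; same LS-block structure as the
#' full model with 7x7 / 3x3 kernels and 4 groups per stage.
#'
#' @param num_classes Number of classes.
#' @param input_size Input spatial size (default 32).
#' @return An `lsnet_config`.
#' @export
lsnet_micro_config <- function(num_classes = 3L, input_size = c(32L, 32L)) {
  stages <- list(
    list(out_channels = 8L, num_blocks = 1L, k_large = 7L, k_small = 3L,
         groups = 4L),
    list(out_channels = 16L, num_blocks = 1L, k_large = 7L, k_small = 3L,
         groups = 4L))
  lsnet_config(stem_channels = 8L, stages = stages,
               num_classes = num_classes, input_size = input_size)
}

#' Spatial resolution entering each stage
#'
#' The stem halves the resolution twice before stage 1's blocks, and each
#' later stage halves it once on entry; the tensor *entering* stage 1 is the
#' raw image. For the default 224x224 configuration this yields
#' 224, 56, 28, 14.
#'
#' @param cfg An `lsnet_config`.
#' @return Integer matrix with one row per stage, columns `H`, `W`.
#' @export
lsnet_stage_resolutions <- function(cfg) {
  n <- length(cfg$stages)
  div <- c(1L, 4L * 2L^(seq_len(n - 1L) - 1L))
  out <- cbind(H = cfg$input_size[1] %/% div, W = cfg$input_size[2] %/% div)
  rownames(out) <- paste0("stage", seq_len(n))
  out
}

# ---- parameter initialization --------------------------------------------

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

init_lsnet_params <- function(cfg) {
  p <- list()
  c1 <- cfg$stem_channels
  cs1 <- cfg$stages[[1]]$out_channels
  p[["stem.conv1.w"]] <- he_init(c(3L, 3L, 3L, c1), 27)
  p[["stem.conv1.b"]] <- numeric(c1)
  p[["stem.conv2.w"]] <- he_init(c(3L, 3L, c1, cs1), 9 * c1)
  p[["stem.conv2.b"]] <- numeric(cs1)
  cprev <- cs1
  for (i in seq_along(cfg$stages)) {
    st <- cfg$stages[[i]]
    C <- st$out_channels
    if (i > 1L) {
      p[[sprintf("s%d.down.dw.k", i)]] <- he_init(c(3L, 3L, cprev), 9)
      p[[sprintf("s%d.down.pw.w", i)]] <- he_init(c(cprev, C), cprev)
      p[[sprintf("s%d.down.pw.b", i)]] <- numeric(C)
    }
    D <- st$groups * st$k_small^2
    for (j in seq_len(st$num_blocks)) {
      pre <- sprintf("s%d.b%d.", i, j)
      if (cfg$normalization == "layernorm") {
        p[[paste0(pre, "norm1.gamma")]] <- rep(1, C)
        p[[paste0(pre, "norm1.beta")]] <- numeric(C)
      }
      p[[paste0(pre, "lkp.pw1.w")]] <- he_init(c(C, C %/% 2L), C)
      p[[paste0(pre, "lkp.pw1.b")]] <- numeric(C %/% 2L)
      p[[paste0(pre, "lkp.dw.k")]] <- he_init(c(st$k_large, st$k_large,
                                                C %/% 2L), st$k_large^2)
      p[[paste0(pre, "lkp.dw.b")]] <- numeric(C %/% 2L)
      # near-zero init: dynamic kernels start small, block starts near identity
      p[[paste0(pre, "lkp.pw2.w")]] <- array(
        stats::rnorm((C %/% 2L) * D, sd = 0.02), dim = c(C %/% 2L, D))
      p[[paste0(pre, "lkp.pw2.b")]] <- numeric(D)
      p[[paste0(pre, "ffn.pw1.w")]] <- he_init(c(C, 2L * C), C)
      p[[paste0(pre, "ffn.pw1.b")]] <- numeric(2L * C)
      p[[paste0(pre, "ffn.pw2.w")]] <- he_init(c(2L * C, C), 2 * C)
      p[[paste0(pre, "ffn.pw2.b")]] <- numeric(C)
    }
    cprev <- C
  }
  p[["head.dense.w"]] <- he_init(c(cprev, cfg$num_classes), cprev)
  p[["head.dense.b"]] <- numeric(cfg$num_classes)
  p
}

#' Build an LS network
#'
#' Allocates and seeds all parameters for the configured backbone. Two
#' builds from the same configuration and seed are bitwise identical.
#'
#' @param cfg An `lsnet_config`.
#' @param seed Integer seed for parameter initialization.
#' @return An object of class `lsnet`: list with `cfg` and `params` (ordered
#'   name -> array mapping).
#' @export
build_lsnet <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "lsnet_config"))
  params <- with_seed(seed, init_lsnet_params(cfg))
  structure(list(cfg = cfg, params = params), class = "lsnet")
}

# ---- LKP / SKA -----------------------------------------------------------

# Internal LKP with cache; params accessed through prefix `pre`.
lkp_fwd <- function(x, params, pre, keep = FALSE) {
  C <- dim(x)[4]
  if (C %% 2L != 0L) stop("LKP requires an even channel count, got ", C)
  f1 <- pw_forward(x, params[[paste0(pre, "pw1.w")]],
                   params[[paste0(pre, "pw1.b")]])
  kdim <- dim(params[[paste0(pre, "dw.k")]])[1]
  if (kdim %% 2L == 0L) stop("LKP large kernel must be odd, got ", kdim)
  f2 <- dw_forward(f1$y, params[[paste0(pre, "dw.k")]],
                   params[[paste0(pre, "dw.b")]])
  f3 <- pw_forward(f2$y, params[[paste0(pre, "pw2.w")]],
                   params[[paste0(pre, "pw2.b")]])
  cache <- if (keep) list(f1 = f1, f2 = f2, f3 = f3) else NULL
  list(w = f3$y, cache = cache)
}

lkp_bwd <- function(dw, cache, params, pre, genv) {
  b3 <- pw_backward(dw, cache$f3, params[[paste0(pre, "pw2.w")]])
  gacc(genv, paste0(pre, "pw2.w"), b3$dw)
  gacc(genv, paste0(pre, "pw2.b"), b3$db)
  b2 <- dw_backward(b3$dx, cache$f2, params[[paste0(pre, "dw.k")]])
  gacc(genv, paste0(pre, "dw.k"), b2$dk)
  gacc(genv, paste0(pre, "dw.b"), b2$db)
  b1 <- pw_backward(b2$dx, cache$f1, params[[paste0(pre, "pw1.w")]])
  gacc(genv, paste0(pre, "pw1.w"), b1$dw)
  gacc(genv, paste0(pre, "pw1.b"), b1$db)
  b1$dx
}

# Internal SKA with cache. Weight channel d = (g-1)*Ks^2 + j indexes kernel
# cell j (column-major within the Ks x Ks window) of group g's kernel.
ska_fwd <- function(x, w, G, ks, keep = FALSE) {
  d <- dim(x)
  C <- d[4]
  if (C %% G != 0L)
    stop("channel count ", C, " not divisible by groups ", G)
  dw <- dim(w)
  if (!all(dw[1:3] == d[1:3]))
    stop("perception weights not spatially aligned with input")
  if (dw[4] != G * ks^2)
    stop("perception weights have ", dw[4], " channels; expected G*Ks^2 = ",
         G * ks^2)
  cg <- C %/% G
  p <- (ks - 1L) %/% 2L
  xp <- pad_hw(x, p)
  expand <- rep(seq_len(G), each = cg)
  out <- array(0, dim = d)
  for (j in seq_len(ks^2)) {
    a <- (j - 1L) %% ks + 1L
    bb <- (j - 1L) %/% ks + 1L
    wj <- w[, , , (seq_len(G) - 1L) * ks^2 + j, drop = FALSE]
    wexp <- wj[, , , expand, drop = FALSE]
    sl <- xp[, a:(a + d[2] - 1L), bb:(bb + d[3] - 1L), , drop = FALSE]
    out <- out + sl * wexp
  }
  cache <- if (keep) list(xp = xp, w = w, G = G, ks = ks, in_dim = d) else NULL
  list(y = out, cache = cache)
}

ska_bwd <- function(dy, cache) {
  d <- cache$in_dim
  G <- cache$G
  ks <- cache$ks
  C <- d[4]
  cg <- C %/% G
  p <- (ks - 1L) %/% 2L
  bhw <- d[1] * d[2] * d[3]
  expand <- rep(seq_len(G), each = cg)
  dxp <- zeros_like(cache$xp)
  dwt <- zeros_like(cache$w)
  for (j in seq_len(ks^2)) {
    a <- (j - 1L) %% ks + 1L
    bb <- (j - 1L) %/% ks + 1L
    sel <- (seq_len(G) - 1L) * ks^2 + j
    wj <- cache$w[, , , sel, drop = FALSE]
    wexp <- wj[, , , expand, drop = FALSE]
    sl <- cache$xp[, a:(a + d[2] - 1L), bb:(bb + d[3] - 1L), , drop = FALSE]
    dxp[, a:(a + d[2] - 1L), bb:(bb + d[3] - 1L), ] <-
      dxp[, a:(a + d[2] - 1L), bb:(bb + d[3] - 1L), , drop = FALSE] +
      dy * wexp
    pr <- dy * sl
    q <- array(pr, dim = c(bhw, cg, G))
    gs <- q[, 1, ]
    if (cg > 1L) for (m in 2:cg) gs <- gs + q[, m, ]
    dwt[, , , sel] <- array(gs, dim = c(d[1], d[2], d[3], G))
  }
  list(dx = unpad_hw(dxp, p, d[2], d[3]), dw = dwt)
}

#' Large-kernel perception: position-wise dynamic kernel generation
#'
#' Applies the bottleneck pipeline pointwise (C -> C/2), depthwise
#' `k_large` x `k_large`, pointwise (C/2 -> G * k_small^2) to produce, at
#' every spatial position, one `k_small` x `k_small` kernel per channel
#' group. Spatial size is preserved by zero padding.
#'
#' @param x Feature map, array `(batch, H, W, C)` with `C` even.
#' @param params Named list with `pw1.w`, `pw1.b`, `dw.k`, `dw.b`, `pw2.w`,
#'   `pw2.b` (shapes as produced by [build_lsnet()]).
#' @param groups Number of channel groups G.
#' @param k_small Small (aggregation) kernel size.
#' @return Array `(batch, H, W, G * k_small^2)` of perception weights, with
#'   attributes `groups` and `k_small`.
#' @export
lkp_forward <- function(x, params, groups, k_small) {
  w <- lkp_fwd(x, params, pre = "", keep = FALSE)$w
  if (dim(w)[4] != groups * k_small^2)
    stop("params produce ", dim(w)[4], " weight channels; expected ",
         groups * k_small^2)
  attr(w, "groups") <- groups
  attr(w, "k_small") <- k_small
  w
}

#' Small-kernel aggregation: grouped dynamic convolution
#'
#' Convolves each position's `k_small` x `k_small` neighborhood with the
#' position-specific kernel emitted by large-kernel perception. All channels
#' in the same group share one kernel per position; output shape equals
#' input shape (zero padding, applied as a sliding inner product).
#'
#' @param x Feature map `(batch, H, W, C)`; `C` divisible by `groups`.
#' @param w Perception weights `(batch, H, W, groups * k_small^2)`.
#' @param groups Number of channel groups (default taken from `attr(w)`).
#' @param k_small Kernel size (default taken from `attr(w)`).
#' @return Aggregated feature map, same shape as `x`.
#' @export
ska_aggregate <- function(x, w, groups = attr(w, "groups"),
                          k_small = attr(w, "k_small")) {
  if (is.null(groups) || is.null(k_small))
    stop("groups/k_small not supplied and not present as attributes of w")
  ska_fwd(x, w, groups, k_small, keep = FALSE)$y
}

# ---- LS block ------------------------------------------------------------
# norm -> LS convolution (LKP then SKA) -> residual add ->
# pointwise FFN (2x expansion, GELU) -> residual add.

block_forward <- function(x, params, pre, st, normalization,
                          keep = FALSE) {
  if (normalization == "layernorm") {
    nf <- ln_forward(x, params[[paste0(pre, "norm1.gamma")]],
                     params[[paste0(pre, "norm1.beta")]])
    z <- nf$y
  } else {
    nf <- NULL
    z <- x
  }
  lk <- lkp_fwd(z, params, paste0(pre, "lkp."), keep = keep)
  sk <- ska_fwd(z, lk$w, st$groups, st$k_small, keep = keep)
  x1 <- x + sk$y
  f1 <- pw_forward(x1, params[[paste0(pre, "ffn.pw1.w")]],
                   params[[paste0(pre, "ffn.pw1.b")]])
  g1 <- gelu_forward(f1$y)
  f2 <- pw_forward(g1$y, params[[paste0(pre, "ffn.pw2.w")]],
                   params[[paste0(pre, "ffn.pw2.b")]])
  y <- x1 + f2$y
  cache <- if (keep) list(nf = nf, lk = lk$cache, sk = sk$cache,
                          f1 = f1, g1 = g1, f2 = f2) else NULL
  list(y = y, cache = cache)
}

block_backward <- function(dy, cache, params, pre, st, normalization, genv) {
  b2 <- pw_backward(dy, cache$f2, params[[paste0(pre, "ffn.pw2.w")]])
  gacc(genv, paste0(pre, "ffn.pw2.w"), b2$dw)
  gacc(genv, paste0(pre, "ffn.pw2.b"), b2$db)
  dg <- gelu_backward(b2$dx, cache$g1)
  b1 <- pw_backward(dg, cache$f1, params[[paste0(pre, "ffn.pw1.w")]])
  gacc(genv, paste0(pre, "ffn.pw1.w"), b1$dw)
  gacc(genv, paste0(pre, "ffn.pw1.b"), b1$db)
  dx1 <- dy + b1$dx
  skb <- ska_bwd(dx1, cache$sk)
  dz <- skb$dx + lkp_bwd(skb$dw, cache$lk, params, paste0(pre, "lkp."), genv)
  if (normalization == "layernorm") {
    lb <- ln_backward(dz, cache$nf, params[[paste0(pre, "norm1.gamma")]])
    gacc(genv, paste0(pre, "norm1.gamma"), lb$dgamma)
    gacc(genv, paste0(pre, "norm1.beta"), lb$dbeta)
    dx1 + lb$dx
  } else {
    dx1 + dz
  }
}

# ---- full network forward / backward -------------------------------------

net_forward <- function(cfg, params, x, keep = FALSE) {
  d <- dim(x)
  if (length(d) != 4L || d[4] != 3L)
    stop("input must be (batch, H, W, 3)")
  if (any(d[2:3] %% (4L * 2L^(length(cfg$stages) - 1L)) != 0L))
    stop("input spatial size not divisible by cumulative downsampling")
  cc <- list()
  c1 <- conv_forward(x, params[["stem.conv1.w"]], params[["stem.conv1.b"]],
                     stride = 2L)
  a1 <- gelu_forward(c1$y)
  c2 <- conv_forward(a1$y, params[["stem.conv2.w"]], params[["stem.conv2.b"]],
                     stride = 2L)
  a2 <- gelu_forward(c2$y)
  h <- a2$y
  if (keep) cc$stem <- list(c1 = c1, a1 = a1, c2 = c2, a2 = a2)
  cc$stages <- list()
  for (i in seq_along(cfg$stages)) {
    st <- cfg$stages[[i]]
    sc <- list()
    if (i > 1L) {
      dn <- dws_forward(h, params[[sprintf("s%d.down.dw.k", i)]])
      pwd <- pw_forward(dn$y, params[[sprintf("s%d.down.pw.w", i)]],
                        params[[sprintf("s%d.down.pw.b", i)]])
      h <- pwd$y
      if (keep) sc$down <- list(dn = dn, pwd = pwd)
    }
    sc$blocks <- list()
    for (j in seq_len(st$num_blocks)) {
      bf <- block_forward(h, params, sprintf("s%d.b%d.", i, j), st,
                          cfg$normalization, keep = keep)
      h <- bf$y
      if (keep) sc$blocks[[j]] <- bf$cache
    }
    if (keep) cc$stages[[i]] <- sc
  }
  gp <- gap_forward(h)
  de <- dense_forward(gp$y, params[["head.dense.w"]], params[["head.dense.b"]])
  if (keep) cc$head <- list(gp = gp, de = de)
  list(logits = de$y, cache = if (keep) cc else NULL)
}

gacc <- function(genv, name, val) {
  if (is.null(genv$g[[name]])) genv$g[[name]] <- val
  else genv$g[[name]] <- genv$g[[name]] + val
}

net_backward <- function(cfg, params, cache, dlogits) {
  genv <- new.env(parent = emptyenv())
  genv$g <- list()
  db <- dense_backward(dlogits, cache$head$de, params[["head.dense.w"]])
  gacc(genv, "head.dense.w", db$dw)
  gacc(genv, "head.dense.b", db$db)
  dh <- gap_backward(db$dx, cache$head$gp)
  for (i in rev(seq_along(cfg$stages))) {
    st <- cfg$stages[[i]]
    sc <- cache$stages[[i]]
    for (j in rev(seq_len(st$num_blocks))) {
      dh <- block_backward(dh, sc$blocks[[j]], params,
                           sprintf("s%d.b%d.", i, j), st, cfg$normalization,
                           genv)
    }
    if (i > 1L) {
      bp <- pw_backward(dh, sc$down$pwd, params[[sprintf("s%d.down.pw.w", i)]])
      gacc(genv, sprintf("s%d.down.pw.w", i), bp$dw)
      gacc(genv, sprintf("s%d.down.pw.b", i), bp$db)
      bd <- dws_backward(bp$dx, sc$down$dn, params[[sprintf("s%d.down.dw.k", i)]])
      gacc(genv, sprintf("s%d.down.dw.k", i), bd$dk)
      dh <- bd$dx
    }
  }
  b2 <- gelu_backward(dh, cache$stem$a2)
  cb2 <- conv_backward(b2, cache$stem$c2, params[["stem.conv2.w"]])
  gacc(genv, "stem.conv2.w", cb2$dw)
  gacc(genv, "stem.conv2.b", cb2$db)
  b1 <- gelu_backward(cb2$dx, cache$stem$a1)
  cb1 <- conv_backward(b1, cache$stem$c1, params[["stem.conv1.w"]])
  gacc(genv, "stem.conv1.w", cb1$dw)
  gacc(genv, "stem.conv1.b", cb1$db)
  list(grads = genv$g[names(params)[names(params) %in% names(genv$g)]],
       dx = cb1$dx)
}

#' Forward pass through an LS network
#'
#' @param model An `lsnet` object from [build_lsnet()].
#' @param x Input images, array `(batch, H, W, 3)`.
#' @param params Optional parameter list overriding `model$params`.
#' @return Logit matrix `(batch, num_classes)`.
#' @export
lsnet_forward <- function(model, x, params = model$params) {
  net_forward(model$cfg, params, x, keep = FALSE)$logits
}

# Softmax cross-entropy over logit rows; labels are 1-based class indices.
softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

lsnet_loss_grad_at <- function(cfg, params, x, y1) {
  fwd <- net_forward(cfg, params, x, keep = TRUE)
  p <- softmax_rows(fwd$logits)
  n <- nrow(p)
  idx <- cbind(seq_len(n), y1)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlog <- p
  dlog[idx] <- dlog[idx] - 1
  dlog <- dlog / n
  bwd <- net_backward(cfg, params, fwd$cache, dlog)
  list(loss = loss, grads = bwd$grads, probs = p, dx = bwd$dx)
}

# ---- accounting ----------------------------------------------------------

#' Count parameters and FLOPs of a built network
#'
#' Parameter count sums tensor element counts. The FLOP count is the number
#' of multiply-accumulate operations of the convolutions and the dense head
#' for one image (convention: 1 MAC = 1 FLOP; normalizations and
#' activations are not counted), stated in the `convention` field.
#'
#' @param model An `lsnet` object.
#' @param input_size Spatial size `c(H, W)`; defaults to the configured one.
#' @return List with `param_count`, `flop_count`, `convention`.
#' @export
count_params_flops <- function(model, input_size = model$cfg$input_size) {
  if (length(input_size) == 1L) input_size <- rep(input_size, 2L)
  cfg <- model$cfg
  param_count <- sum(vapply(model$params, length, integer(1)))
  H <- input_size[1]; W <- input_size[2]
  fl <- (H / 2) * (W / 2) * 9 * 3 * cfg$stem_channels +
    (H / 4) * (W / 4) * 9 * cfg$stem_channels * cfg$stages[[1]]$out_channels
  cprev <- cfg$stages[[1]]$out_channels
  r <- c(H, W) / 4
  for (i in seq_along(cfg$stages)) {
    st <- cfg$stages[[i]]
    C <- st$out_channels
    if (i > 1L) {
      r <- r / 2
      fl <- fl + prod(r) * (9 * cprev + cprev * C)
    }
    D <- st$groups * st$k_small^2
    per_block <- prod(r) * (C * (C / 2) +            # LKP pw1
                            st$k_large^2 * (C / 2) + # LKP depthwise
                            (C / 2) * D +            # LKP pw2
                            st$k_small^2 * C +       # SKA
                            C * 2 * C + 2 * C * C)   # FFN
    fl <- fl + st$num_blocks * per_block
    cprev <- C
  }
  fl <- fl + cprev * cfg$num_classes
  list(param_count = param_count, flop_count = fl,
       convention = "multiply-accumulate operations (1 MAC = 1 FLOP), convolutions and dense head only")
}

# ---- parameter vector utilities ------------------------------------------

#' Flatten a parameter list to a single numeric vector
#' @param params Named list of numeric arrays.
#' @return Numeric vector.
#' @export
flatten_params <- function(params) unlist(params, use.names = FALSE)

#' Restore a parameter list from a flat vector
#' @param vec Numeric vector from [flatten_params()].
#' @param template Parameter list supplying names and shapes.
#' @return Named list of arrays shaped like `template`.
#' @export
unflatten_params <- function(vec, template) {
  out <- template
  pos <- 0L
  for (n in names(template)) {
    len <- length(template[[n]])
    v <- vec[(pos + 1L):(pos + len)]
    if (!is.null(dim(template[[n]]))) dim(v) <- dim(template[[n]])
    out[[n]] <- v
    pos <- pos + len
  }
  if (pos != length(vec)) stop("vector length does not match template")
  out
}
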