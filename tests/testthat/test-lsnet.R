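# Backbone: LKP / SKA primitives against brute-force oracles, shape
# contracts, determinism, gradients, accounting, serialization.

lkp_params_for <- function(C, KL, G, KS, seed = 11) {
  set.seed(seed)
  D <- G * KS^2
  list("pw1.w" = matrix(rnorm(C * C / 2, sd = 0.3), C, C / 2),
       "pw1.b" = rnorm(C / 2, sd = 0.1),
       "dw.k" = array(rnorm(KL * KL * C / 2, sd = 0.2), c(KL, KL, C / 2)),
       "dw.b" = rnorm(C / 2, sd = 0.1),
       "pw2.w" = matrix(rnorm(C / 2 * D, sd = 0.3), C / 2, D),
       "pw2.b" = rnorm(D, sd = 0.1))
}

test_that("LKP matches the nested-loop PW->DW->PW oracle and honors its contract", {
  C <- 8L; KL <- 7L; G <- 4L; KS <- 3L
  p <- lkp_params_for(C, KL, G, KS)
  x <- rand_fmap(21, 1, 8, 8, C)
  w <- lkp_forward(x, p, groups = G, k_small = KS)
  expect_equal(dim(w), c(1L, 8L, 8L, G * KS^2))
  ref <- oracle_pointwise(
    oracle_depthwise(oracle_pointwise(x, p$`pw1.w`, p$`pw1.b`),
                     p$`dw.k`, p$`dw.b`),
    p$`pw2.w`, p$`pw2.b`)
  expect_equal(as.vector(w), as.vector(ref), tolerance = 1e-12)

  # linearity: zero input with zero biases gives zero weights
  p0 <- p
  p0$`pw1.b` <- numeric(C / 2); p0$`dw.b` <- numeric(C / 2)
  p0$`pw2.b` <- numeric(G * KS^2)
  w0 <- lkp_forward(array(0, dim = dim(x)), p0, groups = G, k_small = KS)
  expect_true(all(w0 == 0))

  # configuration errors
  podd <- lkp_params_for(6L, KL, G, KS)
  expect_error(lkp_forward(rand_fmap(1, 1, 4, 4, 7), podd, G, KS), "even")
  peven <- p
  peven$`dw.k` <- array(0, c(6, 6, C / 2))
  expect_error(lkp_forward(x, peven, G, KS), "odd")
})

test_that("SKA matches loop oracles: box filter, identity kernel, group locality", {
  B <- 2L; H <- 6L; W <- 5L; C <- 8L; G <- 4L; KS <- 3L
  x <- rand_fmap(31, B, H, W, C)

  # constant 1/KS^2 kernels reproduce per-channel mean filtering
  wbox <- array(1 / KS^2, dim = c(B, H, W, G * KS^2))
  ybox <- ska_aggregate(x, wbox, groups = G, k_small = KS)
  expect_equal(as.vector(ybox), as.vector(oracle_box_filter(x, KS)),
               tolerance = 1e-12)

  # random dynamic kernels against the full nested-loop oracle
  wr <- rand_fmap(32, B, H, W, G * KS^2)
  expect_equal(as.vector(ska_aggregate(x, wr, G, KS)),
               as.vector(oracle_ska(x, wr, G, KS)), tolerance = 1e-12)

  # one-hot center kernel is the identity map
  wid <- array(0, dim = c(B, H, W, G * KS^2))
  center <- (seq_len(G) - 1L) * KS^2 + (KS^2 + 1L) / 2L
  wid[, , , center] <- 1
  expect_equal(ska_aggregate(x, wid, G, KS), x, tolerance = 1e-14)

  # perturbing group g's kernels only changes that group's channels
  w2 <- wr
  w2[, , , (KS^2 + 1):(2 * KS^2)] <- w2[, , , (KS^2 + 1):(2 * KS^2)] + 0.5
  y1 <- ska_aggregate(x, wr, G, KS)
  y2 <- ska_aggregate(x, w2, G, KS)
  changed <- apply(abs(y2 - y1) > 1e-12, 4, any)
  expect_equal(which(changed), 3:4)  # group 2 holds channels 3-4

  expect_error(ska_aggregate(rand_fmap(1, 1, 4, 4, 6),
                             rand_fmap(2, 1, 4, 4, G * KS^2), G, KS),
               "divisible")
  expect_error(ska_aggregate(x, wr[, 1:4, , , drop = FALSE], G, KS),
               "aligned")
})

test_that("built networks honor shape, resolution, and determinism contracts", {
  cfg <- lsnet_micro_config(num_classes = 3L)
  m <- build_lsnet(cfg, seed = 4)
  x <- rand_fmap(41, 4, 32, 32, 3)
  x[] <- abs(x) / max(abs(x))
  z <- lsnet_forward(m, x)
  expect_equal(dim(z), c(4L, 3L))
  expect_true(all(is.finite(z)))

  res <- lsnet_stage_resolutions(lsnet_table_config())
  expect_equal(unname(res[2:4, "H"]), c(56L, 28L, 14L))
  expect_equal(unname(res[2:4, "W"]), c(56L, 28L, 14L))

  m2 <- build_lsnet(cfg, seed = 4)
  expect_identical(m$params, m2$params)

  # per-sample independence: batch order permutes outputs, nothing else
  perm <- c(3L, 1L, 4L, 2L)
  zp <- lsnet_forward(m, x[perm, , , , drop = FALSE])
  expect_equal(zp, z[perm, ], tolerance = 1e-12)

  expect_error(lsnet_forward(m, rand_fmap(1, 2, 30, 30, 3)), "divisible")
  expect_error(lsnet_config(8, list(list(out_channels = 9L, num_blocks = 1L,
                                         k_large = 7L, k_small = 3L,
                                         groups = 3L)), 3), "even")
})

test_that("parameter count matches an independent shape-sum oracle and grows with width", {
  cfg <- lsnet_micro_config()
  m <- build_lsnet(cfg, seed = 1)
  acc <- count_params_flops(m)
  oracle <- sum(vapply(m$params, function(p)
    prod(dim(p) %||% length(p)), numeric(1)))
  expect_identical(acc$param_count, as.integer(oracle))
  expect_match(acc$convention, "multiply")

  wide <- lsnet_config(
    stem_channels = 16L,
    stages = list(list(out_channels = 16L, num_blocks = 1L, k_large = 7L,
                       k_small = 3L, groups = 4L),
                  list(out_channels = 32L, num_blocks = 1L, k_large = 7L,
                       k_small = 3L, groups = 4L)),
    num_classes = 3L, input_size = c(32L, 32L))
  expect_gt(count_params_flops(build_lsnet(wide, 1))$param_count,
            acc$param_count)
})

test_that("full LS block gradient w.r.t. input matches finite differences", {
  st <- micro_stage()
  p <- micro_block_params()
  x <- rand_fmap(51, 1, 8, 8, 8)
  fwd <- fllsnet:::block_forward(x, p, "s1.b1.", st, "layernorm", keep = TRUE)
  set.seed(52)
  dy <- array(rnorm(length(fwd$y)), dim = dim(fwd$y))
  genv <- new.env(); genv$g <- list()
  dx <- fllsnet:::block_backward(dy, fwd$cache, p, "s1.b1.", st,
                                 "layernorm", genv)
  proj <- function(xv) {
    xx <- array(xv, dim = dim(x))
    sum(fllsnet:::block_forward(xx, p, "s1.b1.", st, "layernorm")$y * dy)
  }
  set.seed(53)
  picks <- sample(length(x), 16)
  h <- 1e-5
  for (i in picks) {
    xv <- as.vector(x)
    xv[i] <- xv[i] + h; fp <- proj(xv)
    xv[i] <- xv[i] - 2 * h; fm <- proj(xv)
    num <- (fp - fm) / (2 * h)
    expect_equal(dx[i], num, tolerance = 1e-4)
  }
})

test_that("checkpoints round-trip: reloaded parameters reproduce identical logits", {
  cfg <- lsnet_micro_config()
  m <- build_lsnet(cfg, seed = 9)
  x <- rand_fmap(61, 2, 32, 32, 3)
  x[] <- abs(x) / max(abs(x))
  z <- lsnet_forward(m, x)
  f <- tempfile(fileext = ".json")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  expect_equal(names(m2$params), names(m$params))
  expect_equal(lsnet_forward(m2, x), z, tolerance = 1e-15)

  v <- flatten_params(m$params)
  expect_identical(unflatten_params(v, m$params), m$params)
})
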