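# Quality-aware weighting: metric definitions, composite scoring, softmax
# weights, aggregation reduction properties, and the linear convergence
# bound.

test_that("convergence velocity is the endpoint loss change per round", {
  expect_equal(convergence_velocity(c(1.0, 0.8, 0.5, 0.3, 0.2), T = 4), 0.2)
  expect_equal(convergence_velocity(rep(0.7, 6)), 0)
  # magnitude, not sign: rising losses count too
  expect_equal(convergence_velocity(c(0.5, 0.7, 0.9), T = 2), 0.2)
  expect_error(convergence_velocity(c(1, 0.5), T = 0), "T")
  expect_error(convergence_velocity(c(NA, 0.5), T = 1), "endpoints")
})

test_that("training stability is the population variance of the trajectory", {
  expect_equal(training_stability(rep(0.4, 5)), 0)
  # brute-force mean-of-squared-deviations: mean((0,2) - 1)^2 = 1
  expect_equal(training_stability(c(0, 2)), 1.0)
  set.seed(3)
  h <- runif(7)
  expect_equal(training_stability(h + 3.7), training_stability(h),
               tolerance = 1e-12)
  expect_equal(training_stability(h), mean((h - mean(h))^2))
  expect_error(training_stability(0.5), "insufficient")
})

test_that("data reliability is the mean confidence and is range-checked", {
  expect_equal(data_reliability(rep(1, 10)), 1)
  expect_equal(data_reliability(c(0.5, 1.0)), 0.75)
  expect_error(data_reliability(numeric(0)), "non-empty")
  expect_error(data_reliability(c(0.5, 1.2)), "\\[0, 1\\]")
  ev <- matrix(c(0, 0, 0, 9, 3, 0), 2, 3, byrow = TRUE)
  expect_equal(evidential_confidence(ev), c(0, 1 - 3 / 15))
})

test_that("composite scores match a step-by-step spreadsheet oracle", {
  cfg <- weighting_config()
  met <- data.frame(c = c(0.30, 0.10, 0.20), s = c(0.04, 0.01, 0.09),
                    q = c(0.90, 0.70, 0.80))
  # independent oracle: z-score each metric with population sigma, sum
  zs <- function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  want <- zs(met$c) + zs(1 / (met$s + cfg$epsilon_stability)) + zs(met$q)
  expect_equal(composite_scores(met, cfg), want, tolerance = 1e-12)

  # identical clients normalize to zero
  same <- data.frame(c = rep(0.2, 4), s = rep(0.03, 4), q = rep(0.8, 4))
  expect_equal(composite_scores(same, cfg), rep(0, 4))

  # z-scores are invariant to a common positive rescaling of one metric
  met2 <- met
  met2$c <- met$c * 50
  expect_equal(composite_scores(met2, cfg), composite_scores(met, cfg),
               tolerance = 1e-9)

  expect_error(weighting_config(gamma2 = 0), "positive")
})

test_that("softmax weights hit closed forms and simplex/shift invariants", {
  expect_equal(softmax_weights(c(2, 2, 2)), rep(1 / 3, 3))
  expect_equal(softmax_weights(c(log(2), 0)), c(2 / 3, 1 / 3))
  set.seed(5)
  for (i in 1:20) {
    s <- rnorm(sample(2:8, 1), sd = 10)
    a <- softmax_weights(s)
    expect_equal(sum(a), 1, tolerance = 1e-9)
    expect_true(all(a > 0))
    expect_equal(softmax_weights(s + 123.4), a, tolerance = 1e-12)
  }
  # overflow-safe for extreme scores
  expect_equal(sum(softmax_weights(c(1e4, 1e4 - 2))), 1)
  expect_error(softmax_weights(c(1, Inf)), "finite")
})

test_that("quality aggregation reduces to FedAvg and respects degenerate weights", {
  set.seed(6)
  plist <- lapply(1:3, function(i) list(w = array(rnorm(4), dim = c(2, 2))))
  hist <- c(1.0, 0.8, 0.6)
  recs_same <- lapply(1:3, function(k)
    list(loss_history = hist, confidence_mean = 0.9))
  agg <- aggregate_fl_lsnet(plist, recs_same, weighting_config(),
                            sizes = c(10, 10, 10))
  ref <- fedavg_aggregate(plist, c(10, 10, 10))
  expect_equal(agg$params, ref)
  expect_equal(agg$weights, rep(1 / 3, 3))

  # degenerate weight vector returns that client's params exactly
  one <- fllsnet:::weighted_param_sum(plist, c(1, 0, 0))
  expect_identical(one$w, plist[[1]]$w)

  # convex combination: outputs stay inside the client envelope
  recs_diff <- lapply(1:3, function(k)
    list(loss_history = hist * k, confidence_mean = 0.5 + 0.1 * k))
  agg2 <- aggregate_fl_lsnet(plist, recs_diff, weighting_config())
  lo <- Reduce(pmin, lapply(plist, `[[`, "w"))
  hi <- Reduce(pmax, lapply(plist, `[[`, "w"))
  expect_true(all(agg2$params$w >= lo - 1e-12 & agg2$params$w <= hi + 1e-12))
  expect_equal(sum(agg2$weights), 1, tolerance = 1e-9)

  # cold start: short histories fall back to size-proportional weights
  recs_short <- lapply(1:3, function(k)
    list(loss_history = 0.5, confidence_mean = 0.9))
  cold <- aggregate_fl_lsnet(plist, recs_short, weighting_config(),
                             sizes = c(1, 1, 2))
  expect_equal(cold$weights, c(0.25, 0.25, 0.5))
})

test_that("a client's weight responds directionally to its own metrics", {
  # Exact sub-property: a client's own z-score is nondecreasing in its own
  # metric (Samuelson's inequality bounds |x_k - mu| by sigma * sqrt(K-1),
  # so the derivative of (x_k - mu)/sigma in x_k is nonnegative).
  set.seed(8)
  for (i in 1:40) {
    x <- runif(sample(2:6, 1))
    k <- sample(length(x), 1)
    x2 <- x; x2[k] <- x2[k] + runif(1, 0.01, 1)
    z1 <- fllsnet:::zscore_pop(x)
    z2 <- fllsnet:::zscore_pop(x2)
    expect_gte(z2[k], z1[k] - 1e-12)
  }
  # Cross-client renormalization couples the weights, so a raw-metric
  # increase lifts the client's weight in the large majority of random
  # configurations and on average, though not in every single one.
  cfg <- weighting_config()
  d_c <- d_q <- d_s <- numeric(200)
  for (i in 1:200) {
    met <- data.frame(c = runif(4, 0, 1), s = runif(4, 0.01, 1),
                      q = runif(4, 0, 1))
    a0 <- softmax_weights(composite_scores(met, cfg))
    up_c <- met; up_c$c[2] <- up_c$c[2] + runif(1, 0.1, 2)
    d_c[i] <- softmax_weights(composite_scores(up_c, cfg))[2] - a0[2]
    up_q <- met; up_q$q[2] <- min(1, up_q$q[2] + runif(1, 0.05, 0.3))
    d_q[i] <- softmax_weights(composite_scores(up_q, cfg))[2] - a0[2]
    up_s <- met; up_s$s[2] <- up_s$s[2] + runif(1, 0.1, 2)
    d_s[i] <- softmax_weights(composite_scores(up_s, cfg))[2] - a0[2]
  }
  expect_gt(mean(d_c >= -1e-12), 0.9)
  expect_gt(mean(d_q >= -1e-12), 0.9)
  expect_gt(mean(d_s <= 1e-12), 0.9)
  expect_gt(mean(d_c), 0)
  expect_gt(mean(d_q), 0)
  expect_lt(mean(d_s), 0)
})

test_that("the linear convergence bound evaluates and contracts as stated", {
  spec <- convergence_bound_spec(mu = 1, L = 1, learning_rate = 0.5,
                                 initial_gap = 1)
  expect_equal(convergence_bound(spec, 2), 0.125)  # (1 - 0.5)^3
  b <- convergence_bound(spec, 0:30)
  expect_true(all(diff(b) < 0))
  expect_lt(b[31], 1e-9)
  expect_warning(
    convergence_bound(convergence_bound_spec(2, 2, 0.6, 1), 1), "vacuous")
  expect_warning(
    convergence_bound(convergence_bound_spec(0.1, 5, 0.5, 1), 1)[1],
    "regime")
})

test_that("full-batch GD on strongly convex quadratics stays under the bound", {
  set.seed(10)
  for (rep_ in 1:10) {
    dim_ <- 3L
    mu <- runif(1, 0.2, 2)
    L <- mu * runif(1, 1, 4)
    lam <- c(mu, runif(dim_ - 2, mu, L), L)
    eta <- runif(1, 0.05, 0.95) / L       # admissible: eta < 2/L, eta*mu < 1
    wstar <- rnorm(dim_)
    w <- wstar + rnorm(dim_, sd = 2)
    gap0 <- sum(0.5 * lam * (w - wstar)^2)
    spec <- convergence_bound_spec(mu, L, eta, gap0)
    for (t in 0:39) {
      w <- w - eta * lam * (w - wstar)      # gradient step
      gap <- sum(0.5 * lam * (w - wstar)^2) # gap after t+1 updates
      expect_lte(gap, convergence_bound(spec, t) + 1e-12)
    }
  }
})
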