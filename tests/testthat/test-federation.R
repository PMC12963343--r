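# Federated loop: local training, size-weighted averaging, participant
# sampling, and full-run behavior against closed forms.

test_that("local training follows the gradient step and handles E = 0", {
  model <- quadratic_fl_model()
  data <- data.frame(a = 1, b = 3)
  fl <- fl_config(num_clients = 1, rounds = 1, local_epochs = 1,
                  participation_ratio = 1, learning_rate = 0.1,
                  optimizer = "gd", batch_size = Inf, weight_decay = 0)
  # w1 = w0 - eta * grad = 0 - 0.1 * (0 - 3) = 0.3
  res <- local_train(model, data, 1L, list(w = 0), fl)
  expect_equal(res$params$w, 0.3, tolerance = 1e-15)
  expect_equal(res$initial_loss, 4.5)

  fl0 <- fl_config(local_epochs = 0, optimizer = "gd")
  res0 <- local_train(model, data, 1L, list(w = 0.7), fl0)
  expect_identical(res0$params, list(w = 0.7))
  expect_error(local_train(model, data, integer(0), list(w = 0), fl),
               "empty")
})

test_that("local epochs reduce the loss on a separable two-class toy", {
  for (sd_ in 1:5) {
    set.seed(sd_)
    n <- 40
    y <- rep(0:1, each = n / 2)
    x <- cbind(rnorm(n, ifelse(y == 0, -2, 2), 0.5),
               rnorm(n, ifelse(y == 0, 1, -1), 0.5))
    model <- logistic_fl_model(2, 2)
    fl <- fl_config(local_epochs = 3, learning_rate = 0.05,
                    optimizer = "sgd", batch_size = 8, weight_decay = 0,
                    seed = sd_)
    res <- local_train(model, list(x = x, y = y), seq_len(n),
                       model$init(sd_), fl)
    expect_lt(res$loss_trace[3], res$loss_trace[1])
  }
})

test_that("size-weighted averaging obeys its algebraic contract", {
  pa <- list(w = array(c(0, 2), dim = c(2, 1)))
  pb <- list(w = array(c(4, 6), dim = c(2, 1)))
  # identical inputs are a fixed point
  same <- fedavg_aggregate(list(pa, pa, pa), c(3, 1, 2))
  expect_equal(same, pa)
  # scalar example: (1*0 + 3*4) / 4 = 3
  expect_equal(fedavg_aggregate(list(list(w = 0), list(w = 4)),
                                c(1, 3))$w, 3)
  # permutation invariance
  expect_equal(fedavg_aggregate(list(pa, pb), c(2, 5)),
               fedavg_aggregate(list(pb, pa), c(5, 2)))
  # envelope: coordinates stay within the client min/max
  set.seed(7)
  plist <- lapply(1:4, function(i) list(w = array(rnorm(6), dim = c(3, 2))))
  sizes <- sample(1:10, 4)
  agg <- fedavg_aggregate(plist, sizes)
  lo <- Reduce(pmin, lapply(plist, `[[`, "w"))
  hi <- Reduce(pmax, lapply(plist, `[[`, "w"))
  expect_true(all(agg$w >= lo - 1e-12 & agg$w <= hi + 1e-12))
  expect_error(fedavg_aggregate(list(pa, list(w = array(0, c(3, 1)))),
                                c(1, 1)), "mismatch")
  expect_error(fedavg_aggregate(list(pa), 0), "positive")
})

test_that("participant sampling rounds half-up and is reproducible", {
  expect_equal(sample_participants(3, 1.0, 1, 42), 1:3)
  expect_length(sample_participants(3, 0.8, 5, 42), 2L)  # round(2.4) = 2
  expect_length(sample_participants(4, 0.875, 1, 42), 4L)  # round(3.5) = 4
  expect_length(sample_participants(10, 0.05, 1, 42), 1L)  # floor of 1
  expect_identical(sample_participants(7, 0.5, 3, 9),
                   sample_participants(7, 0.5, 3, 9))
  expect_error(sample_participants(0, 0.5, 1, 1), "K")
})

test_that("federated averaging on quadratic clients reaches the weighted optimum", {
  qs <- quadratic_shards(17)
  fl <- fl_config(num_clients = 3, rounds = 80, local_epochs = 1,
                  participation_ratio = 1, learning_rate = 0.3,
                  optimizer = "gd", batch_size = Inf, weight_decay = 0,
                  seed = 2)
  h <- run_federated(fl, quadratic_fl_model(0), qs$data, qs$shards,
                     val_fraction = 0)
  n_k <- lengths(qs$shards)
  p_k <- n_k / sum(n_k)
  Eab <- vapply(qs$shards, function(s) mean(qs$data$a[s] * qs$data$b[s]),
                numeric(1))
  Ea <- vapply(qs$shards, function(s) mean(qs$data$a[s]), numeric(1))
  wstar <- sum(p_k * Eab) / sum(p_k * Ea)
  expect_equal(h$final_params$w, wstar, tolerance = 1e-8)
  expect_length(h$rounds, 80L)
  # recorded weights live on the simplex
  for (lg in h$rounds) expect_equal(sum(lg$weights), 1, tolerance = 1e-9)
})

test_that("FedProx with mu = 0 reproduces FedAvg bitwise; mu > 0 stays closer to the anchor", {
  qs <- quadratic_shards(23)
  base <- fl_config(num_clients = 3, rounds = 6, local_epochs = 2,
                    participation_ratio = 1, learning_rate = 0.1,
                    optimizer = "sgd", batch_size = 10, weight_decay = 0,
                    seed = 5, fedprox_mu = 0)
  h_avg <- run_federated(base, quadratic_fl_model(0), qs$data, qs$shards,
                         strategy = "fedavg", val_fraction = 0)
  h_prox0 <- run_federated(base, quadratic_fl_model(0), qs$data, qs$shards,
                           strategy = "fedprox", val_fraction = 0)
  expect_identical(h_avg$final_params, h_prox0$final_params)

  # a strong proximal pull keeps the one-round update closer to the anchor
  anchor <- list(w = 0)
  flp <- fl_config(local_epochs = 5, learning_rate = 0.1, optimizer = "sgd",
                   batch_size = 10, weight_decay = 0, fedprox_mu = 5,
                   seed = 5)
  free <- local_train(quadratic_fl_model(0), qs$data, qs$shards[[3]],
                      anchor, flp, strategy = "fedavg")
  prox <- local_train(quadratic_fl_model(0), qs$data, qs$shards[[3]],
                      anchor, flp, strategy = "fedprox")
  expect_lt(abs(prox$params$w), abs(free$params$w))
})

test_that("a single-client federation equals centralized training", {
  set.seed(9)
  n <- 30
  y <- rep(0:1, each = n / 2)
  x <- cbind(rnorm(n, ifelse(y == 0, -1, 1)), rnorm(n))
  data <- list(x = x, y = y)
  model <- logistic_fl_model(2, 2)
  fl <- fl_config(num_clients = 1, rounds = 4, local_epochs = 1,
                  participation_ratio = 1, learning_rate = 0.05,
                  optimizer = "adam", batch_size = 8, seed = 3)
  h <- run_federated(fl, model, data, list(seq_len(n)), val_fraction = 0)
  cen <- train_centralized(fl, model, data, seq_len(n))
  expect_identical(h$final_params, cen$params)
  expect_equal(vapply(h$rounds, function(r) r$local_losses, numeric(1)),
               cen$loss)
})

test_that("runs are reproducible and conserve sample counts", {
  qs <- quadratic_shards(29)
  fl <- fl_config(num_clients = 3, rounds = 8, local_epochs = 1,
                  participation_ratio = 0.8, learning_rate = 0.1,
                  optimizer = "sgd", batch_size = 16, weight_decay = 0,
                  seed = 11, strategy = "fl-lsnet")
  h1 <- run_federated(fl, quadratic_fl_model(0), qs$data, qs$shards)
  h2 <- run_federated(fl, quadratic_fl_model(0), qs$data, qs$shards)
  expect_identical(h1$final_params, h2$final_params)
  expect_identical(summarize_history(h1), summarize_history(h2))
  expect_equal(sum(vapply(h1$records, `[[`, numeric(1), "n_k")),
               nrow(qs$data))
})

test_that("with IID equal-size shards the quality weights hover near 1/K", {
  for (sd_ in 1:5) {
    set.seed(sd_)
    data <- data.frame(a = runif(150, 0.5, 2), b = rnorm(150, 2, 1))
    shards <- split(sample(150), rep(1:3, each = 50))
    fl <- fl_config(num_clients = 3, rounds = 10, local_epochs = 1,
                    participation_ratio = 1, learning_rate = 0.05,
                    optimizer = "sgd", batch_size = 10, weight_decay = 0,
                    seed = sd_, strategy = "fl-lsnet")
    h <- run_federated(fl, quadratic_fl_model(0), data, shards)
    w_last <- h$rounds[[10]]$weights
    expect_true(all(abs(w_last - 1 / 3) < 0.1))
  }
})
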