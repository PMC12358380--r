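test_that("analytic gradients match central finite differences for every
           parameter group", {
  m <- tiny_model(N = 2, d = 3, layers = 2, d_encoder = 2, d_hidden = 3,
                  seed = 51)
  traj <- toy_traj(T_ = 5, N = 2, seed = 52)
  # jitter away from the exact ReLU/kink points of the zero-bias
  # initialization, where one-sided subgradients and central differences
  # legitimately disagree
  set.seed(99)
  theta <- endoreg:::flatten_params(m$par) +
    stats::runif(length(endoreg:::flatten_params(m$par)), -0.05, 0.05)
  m$par <- endoreg:::relist_params(theta, m$par)
  res <- forecaster_traj_grad(m, traj)
  loss_at <- function(v) {
    mm <- m
    mm$par <- endoreg:::relist_params(v, m$par)
    forecaster_traj_grad(mm, traj, want_grad = FALSE)$loss
  }
  fd <- fd_grad(loss_at, theta, eps = 1e-5)
  rel <- abs(fd - res$gflat) / pmax(abs(fd), 1e-6)
  expect_lt(max(rel), 1e-4) # every parameter, all groups
})

test_that("training is a deterministic no-op at zero epochs and
           reproducible by seed", {
  fx <- fixture_suite("linear_2g")
  data <- generate_dataset(fx$network,
                           synthetic_dataset_spec(8, horizon = 2,
                                                  step = 0.2, seed = 3))
  m <- tiny_model(N = 2, seed = 53, adjacency = fx$network$coupling != 0)
  r0 <- train_forecaster(m, data, training_config(max_epochs = 0))
  expect_identical(r0$model$par, m$par)
  expect_equal(nrow(r0$history), 0)
  cfg <- training_config(max_epochs = 4, batch_size = 4, seed = 42)
  r1 <- train_forecaster(m, data, cfg)
  r2 <- train_forecaster(m, data, cfg)
  expect_identical(r1$history, r2$history) # bitwise determinism
  expect_identical(r1$model$par, r2$model$par)
  expect_error(train_forecaster(m, data[1], cfg), "at least two")
})

test_that("training overfits a single noiseless decay trajectory", {
  net <- gland_network("a", matrix(0, 1, 1), degradation = 0.8)
  traj <- simulate_network(net, h0 = 2, horizon = 25, step = 0.05) # 500 steps
  m <- forecaster_init(matrix(0, 1, 1), d = 2, d_encoder = 2, d_hidden = 8,
                       seed = 42)
  # duplicate so a train/validation split exists; dropout off and single-
  # trajectory batches to drive the fit hard
  cfg <- training_config(max_epochs = 80, patience = 80, dropout = 0,
                         learning_rate = 2e-2, lr_decay_every = 50,
                         batch_size = 1, split = c(50, 25, 25), seed = 42)
  fit <- train_forecaster(m, list(traj, traj, traj, traj), cfg)
  expect_lt(utils::tail(fit$history$train, 1), 1e-3)
})

test_that("median training loss decreases on the synthetic suite", {
  fx <- fixture_suite("linear_2g")
  finals <- firsts <- numeric(5)
  for (s in 1:5) {
    data <- generate_dataset(fx$network,
                             synthetic_dataset_spec(10, horizon = 2,
                                                    step = 0.2, seed = s))
    m <- tiny_model(N = 2, seed = s, adjacency = matrix(1, 2, 2) - diag(2))
    hist <- train_forecaster(m, data,
                             training_config(max_epochs = 8,
                                             batch_size = 8,
                                             learning_rate = 2e-3,
                                             seed = s))$history
    firsts[s] <- hist$train[1]
    finals[s] <- utils::tail(hist$train, 1)
  }
  expect_lt(stats::median(finals), stats::median(firsts))
})

test_that("a trained decay model rolls out close to the ODE solution", {
  net <- gland_network("a", matrix(0, 1, 1), degradation = 0.8)
  spec <- synthetic_dataset_spec(20, horizon = 3, step = 0.1,
                                 init_ranges = c(0.5, 2), noise_sd = 0,
                                 seed = 9)
  data <- generate_dataset(net, spec)
  m <- forecaster_init(matrix(0, 1, 1), d = 2, d_encoder = 2, d_hidden = 4,
                       seed = 42)
  cfg <- training_config(max_epochs = 150, patience = 150, dropout = 0,
                         learning_rate = 1e-2, lr_decay_every = 75,
                         batch_size = 4, seed = 42)
  fit <- train_forecaster(m, data, cfg)
  ro <- rollout(fit$model, 1.6, steps = 20, dt = 0.1)
  truth <- 1.6 * exp(-0.8 * 0.1 * (0:20))
  rel <- abs(ro$states[, 1] - truth) / truth
  expect_lt(max(rel), 0.10)
})

test_that("training reports divergence with the epoch index", {
  fx <- fixture_suite("linear_2g")
  data <- generate_dataset(fx$network,
                           synthetic_dataset_spec(4, horizon = 1,
                                                  step = 0.2, seed = 2))
  m <- tiny_model(N = 2, seed = 54, adjacency = matrix(1, 2, 2) - diag(2))
  m$par$readout$b3 <- c(Inf, Inf)
  expect_error(train_forecaster(m, data, training_config(max_epochs = 1)),
               "epoch 1")
})
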