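test_that("forward step is pure and honors a constant readout", {
  m <- tiny_model(N = 2, seed = 41)
  h <- c(1, 0.4); u <- c(0.2, 0)
  f1 <- forward_step(m, h, u)
  f2 <- forward_step(m, h, u)
  expect_identical(f1, f2)
  # zero readout weights with bias c: prediction is c regardless of input
  m0 <- m
  m0$par$readout$W3[] <- 0
  m0$par$readout$b3 <- c(3.5, -1)
  expect_equal(forward_step(m0, h, u)$prediction, c(3.5, -1))
  expect_equal(forward_step(m0, c(9, 9), c(5, 5))$prediction, c(3.5, -1))
  expect_error(forward_step(m, c(1, 2, 3)), "length")
})

test_that("a step replays the stage-by-stage pipeline composition", {
  m <- tiny_model(N = 2, d = 2, d_encoder = 2, d_hidden = 3, seed = 42)
  h <- c(0.8, 1.3); u <- c(0.1, 0.6)
  carry <- zero_carry(m)
  # independent scripted composition out of the exported stage operations
  X0 <- outer(h, m$par$lift$w) + matrix(m$par$lift$b, 2, m$d, byrow = TRUE)
  gp <- endoreg:::model_graph_params(m)
  G <- gnn_forward(X0, m$adjacency, gp)
  uenc <- encode_stimulus(u, endoreg:::model_encoder_params(m))
  Xin <- cbind(h, G, matrix(uenc, 2, m$d_encoder, byrow = TRUE))
  st <- lstm_step(Xin, carry$hidden, carry$cell, do.call(
    recurrent_params, m$par$lstm))
  pred <- as.numeric(m$par$readout$W3 %*% as.numeric(t(st$hidden)) +
                       m$par$readout$b3)
  got <- forward_step(m, h, u, carry)
  expect_equal(got$prediction, pred, tolerance = 1e-10)
  expect_equal(got$carry$hidden, st$hidden, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(got$carry$cell, st$cell, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("mean squared error follows its definition", {
  expect_equal(mse_loss(matrix(1, 3, 2), matrix(1, 3, 2)), 0)
  expect_equal(mse_loss(matrix(3, 1, 1), matrix(1, 1, 1)), 4)
  expect_equal(mse_loss(rbind(c(1, 0), c(0, 1)), matrix(0, 2, 2)), 0.5)
  a <- matrix(stats::runif(6), 3, 2); b <- matrix(stats::runif(6), 3, 2)
  expect_equal(mse_loss(a, b), mse_loss(b, a))
  expect_error(mse_loss(matrix(1, 2, 2), matrix(1, 3, 2)), "shape")
})

test_that("rollout chains predictions autoregressively", {
  m <- tiny_model(N = 2, seed = 43)
  # one step equals forward_step from the initial state
  one <- rollout(m, c(1, 1), steps = 1, dt = 0.1)
  fs <- forward_step(m, c(1, 1), c(0, 0))
  expect_equal(unname(one$states[2, ]), pmax(fs$prediction, 0))
  # constant-readout model is a fixed point after the first step
  m0 <- m
  m0$par$readout$W3[] <- 0
  m0$par$readout$b3 <- c(0.7, 0.2)
  ro <- rollout(m0, c(2, 2), steps = 5, dt = 0.1)
  for (k in 2:6) expect_equal(unname(ro$states[k, ]), c(0.7, 0.2))
  # schedule is sampled on the rollout grid
  sched <- intervention_schedule(1, 2, start = 0.15, end = 0.25)
  ro2 <- rollout(m, c(1, 1), sched, steps = 3, dt = 0.1)
  expect_equal(unname(ro2$inputs[, 1]), c(0, 0, 2, 0))
  expect_error(rollout(m, c(1, 1), steps = 0), "steps")
})

test_that("saved bundles reload identically and validate dimensions", {
  m <- tiny_model(N = 3, d = 4, layers = 2, seed = 44,
                  adjacency = rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  save_forecaster(m, f1)
  m2 <- load_forecaster(f1)
  expect_equal(m2$par, m$par, tolerance = 0) # full-precision round trip
  h <- c(1, 0.5, 2)
  expect_identical(forward_step(m2, h)$prediction,
                   forward_step(m, h)$prediction)
  save_forecaster(m2, f2)
  expect_identical(readLines(f1), readLines(f2)) # save-load idempotent
  # tampered bundle fails the dimension-chain validation
  txt <- readLines(f1)
  txt <- sub('"d": 4', '"d": 5', txt)
  f3 <- tempfile(fileext = ".json")
  writeLines(txt, f3)
  expect_error(load_forecaster(f3), "mismatch")
})
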