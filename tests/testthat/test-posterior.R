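test_that("conjugate linear-Gaussian updates are exact", {
  post <- patient_posterior("theta", mean = 0, cov = 1, noise_sd = 1)
  # no data: posterior equals the prior
  expect_identical(update_posterior(post, NULL, list(type = "direct")),
                   post)
  expect_identical(update_posterior(post, numeric(0),
                                    list(type = "direct")), post)
  # one direct unit-noise observation y = 2 of the parameter itself:
  # precision 1 + 1 = 2, mean (0 + 2)/2 = 1 -> N(1, 0.5)
  up <- update_posterior(post, 2, list(type = "direct",
                                       X = matrix(1, 1, 1)))
  expect_equal(up$mean, 1, tolerance = 1e-12)
  expect_equal(up$cov[1, 1], 0.5, tolerance = 1e-12)
  # posterior sd never exceeds the prior sd for direct observations
  set.seed(41)
  for (rep in 1:20) {
    P <- sample(1:3, 1)
    S0 <- crossprod(rmat(P + 1, P, 1)) + diag(0.2, P)
    prior <- patient_posterior(paste0("p", 1:P), stats::runif(P), S0,
                               noise_sd = stats::runif(1, 0.2, 2))
    n <- sample(1:5, 1)
    X <- rmat(n, P, 1)
    y <- stats::runif(n)
    upd <- update_posterior(prior, y, list(type = "direct", X = X))
    # precision-additivity oracle
    want_prec <- solve(S0) + crossprod(X) / prior$noise_sd^2
    expect_equal(solve(upd$cov), want_prec, tolerance = 1e-8)
    expect_true(all(sqrt(diag(upd$cov)) <= sqrt(diag(S0)) + 1e-12))
  }
})

test_that("patient parameters are recovered from noisy trajectories", {
  fx <- fixture_suite("linear_2g")
  net <- fx$network
  ps <- list(list(kind = "degradation", i = 1),
             list(kind = "coupling", i = 2, j = 1))
  set.seed(7)
  hits <- 0
  n_pat <- 6
  for (pat in seq_len(n_pat)) {
    truth <- c(stats::runif(1, 0.5, 1.1), stats::runif(1, 0.3, 0.9))
    true_net <- endoreg:::apply_patient_params(net, ps, truth)
    tr <- simulate_network(true_net, c(1.5, 1), horizon = 8, step = 0.1)
    obs <- tr
    obs$states <- pmax(tr$states +
                         matrix(stats::rnorm(length(tr$states), 0, 0.05),
                                nrow(tr$states)), 0)
    prior <- patient_posterior(c("gamma1", "beta21"), mean = c(0.8, 0.6),
                               cov = diag(0.09, 2), noise_sd = 0.05)
    up <- update_posterior(prior, obs,
                           model = list(type = "trajectory", network = net,
                                        param_spec = ps, h0 = c(1.5, 1),
                                        horizon = 8, step = 0.1,
                                        schedule = NULL))
    z <- abs(up$mean - truth) / sqrt(diag(up$cov))
    if (all(z <= 2)) hits <- hits + 1
    # the data must dominate the prior at this noise level
    expect_true(all(sqrt(diag(up$cov)) < 0.1))
  }
  expect_gte(hits, n_pat - 1)
})

test_that("transition observations update the posterior toward the truth", {
  fx <- fixture_suite("linear_2g")
  ps <- list(list(kind = "degradation", i = 1))
  truth <- 1.0
  true_net <- endoreg:::apply_patient_params(fx$network, ps, truth)
  transitions <- lapply(seq(0.4, 2, length.out = 8), function(h1) {
    h <- c(h1, 0.7)
    nxt <- endoreg:::plant_step_with_sensitivity(true_net, h,
                                                 c(0.2, 0.1), 0.5)$h
    list(h = h, u = c(0.2, 0.1), h_next = nxt)
  })
  prior <- patient_posterior("gamma1", mean = 0.7, cov = 0.04,
                             noise_sd = 0.02)
  up <- update_posterior(prior, transitions,
                         model = list(type = "transitions",
                                      network = fx$network,
                                      param_spec = ps, dt = 0.5))
  expect_lt(abs(up$mean - truth), 0.05)
  expect_lt(sqrt(up$cov[1, 1]), sqrt(0.04))
})

test_that("posterior validation catches degenerate covariances", {
  expect_error(patient_posterior("a", 0, matrix(-1, 1, 1), 1),
               "positive definite")
  expect_error(patient_posterior("a", 0, 1, 0), "noise_sd")
})
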