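cfg2 <- function(...) control_config(targets = c(1, 1), ...)

test_that("elementary controller quantities follow their definitions", {
  expect_equal(deviation(c(2, 3), c(1, 1)), c(1, 2))
  expect_equal(deviation(c(1, 1), c(1, 1)), c(0, 0))
  a <- stats::runif(4); b <- stats::runif(4)
  expect_equal(deviation(a, b), -deviation(b, a))
  expect_error(deviation(1:2, 1:3), "equal length")

  expect_equal(feedback_loss(c(0, 0)), 0)
  expect_equal(feedback_loss(c(3, 4)), 25)
  v <- stats::runif(6, -2, 2)
  expect_equal(feedback_loss(v), sum(sapply(v, function(x) x^2)),
               tolerance = 1e-12)

  expect_equal(stability_index(c(0, 2), c(2, 0)), 1)
  expect_equal(stability_index(c(0, 0), c(1, 1)), 0)
  expect_equal(stability_index(3, 2), 1.5)
  expect_error(stability_index(c(1, 1), c(0, 0)), "undefined")

  expect_equal(total_deviation(c(1, 1), c(1, 1)), 0)
  expect_equal(total_deviation(c(2, 3), c(1, 1)), 5)

  expect_equal(adapt_learning_rate(0.3, 0, 2), 0.3)
  expect_equal(adapt_learning_rate(0.4, 1, log(2)), 0.2)
  etas <- sapply(c(0, 0.5, 1, 4), function(D) adapt_learning_rate(1, D, 0.7))
  expect_true(all(diff(etas) < 0)) # monotone in D
})

test_that("risk combines intensity and pairwise conflict penalties", {
  rho <- matrix(c(0, 0.5, 0.5, 0), 2)
  expect_equal(risk(c(0, 0), rho), 0)
  expect_equal(risk(c(1, -1), rho), 4) # 2 + 0.5*2 + 0.5*2
  expect_equal(risk(c(0.7, 0.7), rho), 2 * 0.49) # uniform: no conflict term
  # subgradient at ties is zero for the conflict term
  g <- endoreg:::risk_grad(c(0.7, 0.7), rho)
  expect_equal(g, 2 * c(0.7, 0.7))
})

test_that("composite objectives reduce to their parts", {
  cc <- control_config(targets = c(1, 2), weights = c(1, 3),
                       risk_weight = 0.7,
                       interaction_risk = matrix(c(0, .2, .2, 0), 2))
  expect_equal(multi_objective_loss(c(1, 2), c(0, 0), cc), 0)
  cc1 <- control_config(targets = 1, weights = 1, risk_weight = 0)
  expect_equal(multi_objective_loss(2, 5, cc1), 1)
  # random instances vs an independent two-term oracle
  set.seed(17)
  for (rep in 1:20) {
    h <- stats::runif(2, 0, 3); u <- stats::runif(2, -1, 2)
    want <- sum(c(1, 3) * (h - c(1, 2))^2) +
      0.7 * (sum(u^2) + 0.2 * abs(u[1] - u[2]) * 2)
    expect_equal(multi_objective_loss(h, u, cc), want, tolerance = 1e-12)
  }
  # hinge: inactive penalty leaves the loss untouched, active adds linearly
  cc3 <- control_config(targets = c(1, 2), risk_threshold = 10,
                        penalty = 2,
                        interaction_risk = matrix(0, 2, 2))
  u <- c(1, 1) # C(u) = 2 <= 10
  expect_equal(constrained_objective(c(0, 0), u, cc3),
               multi_objective_loss(c(0, 0), u, cc3))
  cc4 <- control_config(targets = c(1, 2), risk_threshold = 1, penalty = 2,
                        interaction_risk = matrix(0, 2, 2))
  expect_equal(constrained_objective(c(0, 0), u, cc4),
               multi_objective_loss(c(0, 0), u, cc4) + 2 * (2 - 1))
  # continuity at the threshold
  eps <- 1e-9
  below <- constrained_objective(c(0, 0), sqrt((1 - eps) / 2) * c(1, 1), cc4)
  above <- constrained_objective(c(0, 0), sqrt((1 + eps) / 2) * c(1, 1), cc4)
  expect_lt(abs(above - below), 1e-7)
})

test_that("intervention updates descend the chosen objective", {
  # identity predictor, observed = 0: L = ||u||^2, one step halves u
  ident <- function(h, u) u
  cc <- control_config(targets = 0, weights = 1, intervention_lr = 0.25)
  u1 <- update_intervention(1, ident, observed = 0, cc, "feedback")
  expect_equal(u1, 0.5)
  # repeated updates converge to the observation
  cc2 <- control_config(targets = 0.7, intervention_lr = 0.25)
  u <- 1
  for (k in 1:50) u <- update_intervention(u, ident, observed = 0.3, cc2,
                                           "feedback")
  expect_lt(abs(u - 0.3), 1e-6)
  # eta = 0 leaves u unchanged (zero step)
  expect_equal(update_intervention(c(1, 2), function(h, u) u, c(0, 0),
                                   cfg2(), "feedback", eta = 0), c(1, 2))
})

test_that("analytic multi-objective gradients match finite differences,
           including near the conflict-term kinks", {
  set.seed(23)
  fx <- fixture_suite("linear_2g")
  pf <- endoreg:::as_predictor(fx$network, dt = 0.5)
  worst <- 0
  for (rep in 1:100) {
    rho <- matrix(stats::runif(4, 0, 1), 2); rho[cbind(1:2, 1:2)] <- 0
    rho <- (rho + t(rho)) / 2
    cc <- control_config(targets = stats::runif(2, 0.5, 2),
                         weights = stats::runif(2, 0.2, 2),
                         risk_weight = stats::runif(1, 0, 1),
                         interaction_risk = rho)
    h <- stats::runif(2, 0.2, 2)
    u <- stats::runif(2, -1, 1)
    if (abs(u[1] - u[2]) < 1e-3) u[1] <- u[1] + 0.01 # stay off the tie
    g <- endoreg:::intervention_gradient(u, pf, h, cc, "multi")$grad
    fd <- fd_grad(function(v) {
      pred <- pf$predict(h, v)
      multi_objective_loss(pred, v, cc)
    }, u)
    worst <- max(worst, max(abs(g - fd) / pmax(abs(fd), 1e-6)))
  }
  expect_lt(worst, 1e-4)
})

test_that("small gradient steps never increase the smooth objective", {
  fx <- fixture_suite("linear_2g")
  pf <- endoreg:::as_predictor(fx$network, dt = 0.5)
  set.seed(31)
  for (eta in c(1e-3, 1e-4)) {
    for (rep in 1:20) {
      cc <- control_config(targets = stats::runif(2, 0.5, 2),
                           weights = c(1, 1), risk_weight = 0.3,
                           interaction_risk = matrix(0, 2, 2),
                           intervention_lr = eta)
      h <- stats::runif(2, 0.2, 2)
      u <- stats::runif(2, 0, 1)
      L0 <- multi_objective_loss(pf$predict(h, u), u, cc)
      u1 <- update_intervention(u, fx$network, h, cc, "multi")
      L1 <- multi_objective_loss(pf$predict(h, u1), u1, cc)
      expect_lte(L1, L0 + 1e-12)
    }
  }
})

test_that("the closed loop regulates a linear plant to reachable targets", {
  fx <- fixture_suite("linear_2g")
  cc <- control_config(targets = c(0.8, 1.2), intervention_lr = 0.5,
                       decay = 0.05, max_iters = 50)
  log <- closed_loop_run(fx$network, cc, h0 = c(1.5, 0.3), horizon = 100)
  expect_lt(log$D[100], 0.01 * log$D[1]) # >= 99% reduction
  # eta = 0 is rejected by the config contract; a no-op controller comes
  # from zero inner iterations instead
  cc0 <- control_config(targets = c(0.8, 1.2), intervention_lr = 0.5,
                        max_iters = 0)
  log0 <- closed_loop_run(fx$network, cc0, h0 = c(1.5, 0.3), horizon = 10,
                          u0 = c(0.3, 0.4))
  for (k in 1:10)
    expect_equal(unname(unlist(log0[k, c("u_A", "u_B")])), c(0.3, 0.4))
})

test_that("large penalties keep every accepted intervention feasible", {
  fx <- fixture_suite("linear_2g")
  rho <- matrix(c(0, 0.4, 0.4, 0), 2)
  cc <- control_config(targets = c(1.5, 2), risk_weight = 0,
                       interaction_risk = rho, risk_threshold = 0.5,
                       penalty = 1e4, intervention_lr = 0.5,
                       max_iters = 100)
  log <- closed_loop_run(fx$network, cc, h0 = c(0.5, 0.5), horizon = 40)
  expect_true(all(log$C_u <= 0.5 + 1e-6))
  # the unconstrained optimum violates the threshold, so the constraint binds
  cc_free <- control_config(targets = c(1.5, 2), intervention_lr = 0.5,
                            max_iters = 100)
  log_free <- closed_loop_run(fx$network, cc_free, h0 = c(0.5, 0.5),
                              horizon = 40)
  expect_gt(max(log_free$C_u), 0.5)
})

test_that("the stability index tracks convergence of the deviations", {
  fx <- fixture_suite("linear_2g")
  cc <- control_config(targets = c(0.8, 1.2), intervention_lr = 0.5,
                       decay = 0.05, max_iters = 50)
  log <- closed_loop_run(fx$network, cc, h0 = c(1.5, 0.3), horizon = 100)
  tail_q <- log[76:100, ]
  # converged steps have identically-zero deviations; any defined index in
  # the final quarter must witness shrinking deviations
  ok <- tail_q$converged | (!is.na(tail_q$stability_index) &
                              tail_q$stability_index < 1)
  expect_true(all(ok))
  expect_true(any(log$converged | (!is.na(log$stability_index) &
                                     log$stability_index < 1)))
})

test_that("a forecaster can stand in as the controller's predictor", {
  m <- tiny_model(N = 2, d = 3, d_encoder = 2, d_hidden = 4, seed = 71)
  set.seed(72)
  theta <- endoreg:::flatten_params(m$par)
  m$par <- endoreg:::relist_params(theta + stats::runif(length(theta),
                                                        -0.05, 0.05),
                                   m$par)
  pf <- endoreg:::as_predictor(m)
  h <- c(1, 0.5); u <- c(0.3, 0.1)
  # backpropagated input-sensitivities match finite differences
  J <- pf$jac_u(h, u)
  for (j in 1:2) {
    fd <- fd_grad(function(x) {
      uu <- u; uu[j] <- x
      pf$predict(h, uu)[1]
    }, u[j])
    expect_equal(J[1, j], fd, tolerance = 1e-6)
  }
  # and the closed loop runs end to end with the neural predictor
  fx <- fixture_suite("linear_2g")
  cc <- control_config(targets = c(0.8, 1.2), intervention_lr = 0.2,
                       max_iters = 10)
  log <- closed_loop_run(fx$network, cc, h0 = c(1.5, 0.3), horizon = 5,
                         predictor = m)
  expect_equal(nrow(log), 5)
  expect_true(all(is.finite(log$D)))
})

test_that("interventions respect the dosage box when configured", {
  fx <- fixture_suite("linear_2g")
  cc <- control_config(targets = c(3, 3), intervention_lr = 1,
                       u_max = 0.2, max_iters = 50)
  log <- closed_loop_run(fx$network, cc, h0 = c(0.1, 0.1), horizon = 10)
  u_cols <- as.matrix(log[, c("u_A", "u_B")])
  expect_true(all(u_cols >= 0 & u_cols <= 0.2 + 1e-12))
})
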