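#' Controller configuration
#'
#' Settings of the adaptive closed-loop intervention optimizer: clinical
#' targets and their weights, the risk penalty, the constraint threshold and
#' penalty strength, the intervention learning rate and its deviation-driven
#' decay.
#'
#' @param targets desired hormone levels `h_i^target` (length `N`).
#' @param weights clinical-importance weights `w_i >= 0` (recycled).
#' @param risk_weight regularization `lambda_risk >= 0` on the risk term.
#' @param interaction_risk `N x N` non-negative matrix `rho[i, j]` with zero
#'   diagonal penalizing disparity between interventions `i` and `j`
#'   (symmetric by default; a scalar is expanded to a constant off-diagonal).
#' @param intervention_lr learning rate `eta > 0` for intervention updates.
#' @param decay deviation-driven learning-rate decay factor `kappa >= 0`.
#' @param risk_threshold allowable risk `epsilon >= 0` of the safety
#'   constraint (default `Inf`: unconstrained).
#' @param penalty constraint penalty strength `lambda >= 0` (default 1e4).
#' @param max_iters inner optimization iterations per control step.
#' @param convergence_tol inner stopping tolerance on the update norm.
#' @param u_max optional box clamp `[0, u_max]` on interventions.
#' @param control_dt plant time advanced per control step.
#' @return an object of class `"control_config"`.
#' @export
control_config <- function(targets, weights = 1, risk_weight = 0,
                           interaction_risk = 0, intervention_lr = 0.5,
                           decay = 0.05, risk_threshold = Inf,
                           penalty = 1e4, max_iters = 50L,
                           convergence_tol = 1e-10, u_max = Inf,
                           control_dt = 1) {
  targets <- as.numeric(targets)
  N <- length(targets)
  weights <- rep_len(as.numeric(weights), N)
  if (any(weights < 0)) stop("weights must be >= 0", call. = FALSE)
  if (risk_weight < 0) stop("risk_weight must be >= 0", call. = FALSE)
  if (!is.matrix(interaction_risk)) {
    rho <- matrix(as.numeric(interaction_risk[1L]), N, N)
    diag(rho) <- 0
  } else rho <- interaction_risk
  if (!all(dim(rho) == c(N, N)) || any(rho < 0) || any(diag(rho) != 0))
    stop("interaction_risk must be N x N, non-negative, zero diagonal",
         call. = FALSE)
  if (intervention_lr <= 0) stop("intervention_lr must be > 0", call. = FALSE)
  if (decay < 0 || risk_threshold < 0 || penalty < 0)
    stop("decay, risk_threshold and penalty must be >= 0", call. = FALSE)
  structure(list(targets = targets, weights = weights,
                 risk_weight = risk_weight, interaction_risk = rho,
                 intervention_lr = intervention_lr, decay = decay,
                 risk_threshold = risk_threshold, penalty = penalty,
                 max_iters = as.integer(max_iters),
                 convergence_tol = convergence_tol, u_max = u_max,
                 control_dt = control_dt),
            class = "control_config")
}

#' Prediction deviation
#'
#' Componentwise prediction error `predicted - observed`.
#' @param predicted,observed equal-length numeric vectors.
#' @return deviation vector.
#' @export
deviation <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("predicted and observed must have equal length", call. = FALSE)
  predicted - observed
}

#' Feedback loss
#'
#' Squared Euclidean norm of a deviation vector.
#' @param dev numeric deviation vector.
#' @return non-negative scalar.
#' @export
feedback_loss <- function(dev) {
  if (any(!is.finite(dev))) stop("deviation must be finite", call. = FALSE)
  sum(dev^2)
}

#' Stability index
#'
#' Ratio of consecutive deviation norms,
#' `||dev_next|| / ||dev_prev||`. Values near 1 indicate steady tracking,
#' below 1 convergence, above 1 divergence. A zero previous deviation makes
#' the index undefined and raises an error (callers log the step as
#' converged instead).
#'
#' @param dev_next,dev_prev deviation vectors.
#' @return non-negative scalar.
#' @export
stability_index <- function(dev_next, dev_prev) {
  np <- sqrt(sum(dev_prev^2))
  if (np == 0)
    stop("stability index undefined: previous deviation is zero",
         call. = FALSE)
  sqrt(sum(dev_next^2)) / np
}

#' Intervention risk
#'
#' `R(u) = ||u||^2 + sum_{i != j} rho[i, j] |u_i - u_j|`: the squared
#' intensity of the intervention plus pairwise disparity penalties for
#' conflicting interventions.
#'
#' @param u intervention vector.
#' @param interaction_risk non-negative zero-diagonal matrix `rho`.
#' @return non-negative scalar.
#' @export
risk <- function(u, interaction_risk) {
  D <- abs(outer(u, u, "-"))
  sum(u^2) + sum(interaction_risk * D)
}

# Subgradient of the risk; the |u_i - u_j| kink at ties contributes 0.
risk_grad <- function(u, rho) {
  S <- sign(outer(u, u, "-"))
  2 * u + rowSums(rho * S) - colSums(rho * S)
}

#' Multi-objective intervention loss
#'
#' `sum_i w_i (h_i - h_i^target)^2 + lambda_risk * R(u)`.
#'
#' @param h hormone vector (typically the predicted next state under `u`).
#' @param u intervention vector.
#' @param config a [control_config()].
#' @return non-negative scalar.
#' @export
multi_objective_loss <- function(h, u, config) {
  sum(config$weights * (h - config$targets)^2) +
    config$risk_weight * risk(u, config$interaction_risk)
}

#' Total deviation from targets
#'
#' `D(t) = sum_i (h_i - h_i^target)^2`, the convergence monitor of the
#' regulation loop.
#' @param h hormone vector.
#' @param targets target vector.
#' @return non-negative scalar.
#' @export
total_deviation <- function(h, targets) sum((h - targets)^2)

#' Deviation-driven learning-rate decay
#'
#' `eta' = eta * exp(-kappa * D)`: the intervention learning rate shrinks
#' when the system is far from target, damping aggressive updates.
#' @param eta current learning rate (`> 0`).
#' @param total_dev total deviation `D >= 0`.
#' @param decay decay factor `kappa >= 0`.
#' @return updated learning rate.
#' @export
adapt_learning_rate <- function(eta, total_dev, decay) {
  stopifnot(eta > 0, total_dev >= 0, decay >= 0)
  eta * exp(-decay * total_dev)
}

#' Constrained intervention objective
#'
#' Penalty form of the risk-constrained problem:
#' `L_multi + lambda * max(0, C(u) - epsilon)` with the safety constraint
#' `C(u)` structurally identical to the risk `R(u)`.
#'
#' @inheritParams multi_objective_loss
#' @return scalar; equals [multi_objective_loss()] whenever `C(u) <= epsilon`.
#' @export
constrained_objective <- function(h, u, config) {
  multi_objective_loss(h, u, config) +
    config$penalty * max(0, risk(u, config$interaction_risk) -
                              config$risk_threshold)
}

# --- Predictor abstraction -------------------------------------------------
# A predictor maps (h_obs, u) to the predicted next state and exposes the
# sensitivity d prediction / d u. Three routes:
#  * gland_network: one RK4 control step with analytic forward sensitivities;
#  * forecaster model/fit: one forward step, input gradients by backprop;
#  * plain function(h, u) (or function(u)): central finite differences
#    (step 1e-5), the documented fallback.
as_predictor <- function(predictor, dt = 1) {
  if (inherits(predictor, "endo_forecaster")) predictor <- predictor$model
  if (inherits(predictor, "gland_network")) {
    net <- predictor
    list(
      predict = function(h, u) plant_step_with_sensitivity(net, h, u, dt)$h,
      jac_u = function(h, u) plant_step_with_sensitivity(net, h, u, dt)$S,
      both = function(h, u) {
        r <- plant_step_with_sensitivity(net, h, u, dt)
        list(pred = r$h, J = r$S)
      }
    )
  } else if (inherits(predictor, "forecaster_model")) {
    model <- predictor
    both <- function(h, u) {
      cc <- forecaster_step_cached(model, h, u, zero_carry(model))
      N <- length(cc$pred)
      J <- matrix(0, N, length(u))
      for (i in seq_len(N)) {
        e <- numeric(N); e[i] <- 1
        bk <- forecaster_step_backward(model, cc, e,
                                       matrix(0, model$n_glands,
                                              model$d_hidden),
                                       matrix(0, model$n_glands,
                                              model$d_hidden))
        J[i, ] <- bk$d_u
      }
      list(pred = cc$pred, J = J)
    }
    list(predict = function(h, u) both(h, u)$pred,
         jac_u = function(h, u) both(h, u)$J,
         both = both)
  } else if (is.function(predictor)) {
    f <- predictor
    call_f <- function(h, u) {
      if (length(formals(f)) >= 2L) f(h, u) else f(u)
    }
    both <- function(h, u) {
      pred <- call_f(h, u)
      J <- matrix(0, length(pred), length(u))
      fd <- 1e-5
      for (j in seq_along(u)) {
        up <- u; up[j] <- up[j] + fd
        um <- u; um[j] <- um[j] - fd
        J[, j] <- (call_f(h, up) - call_f(h, um)) / (2 * fd)
      }
      list(pred = pred, J = J)
    }
    list(predict = call_f, jac_u = function(h, u) both(h, u)$J, both = both)
  } else stop("unsupported predictor", call. = FALSE)
}

# Gradient of the chosen objective with respect to u, through the predictor.
intervention_gradient <- function(u, pred_fns, observed, config,
                                  objective = c("multi", "feedback"),
                                  constrained = FALSE) {
  objective <- match.arg(objective)
  b <- pred_fns$both(observed, u)
  if (objective == "feedback") {
    g <- as.numeric(2 * crossprod(b$J, b$pred - observed))
    loss <- sum((b$pred - observed)^2)
  } else {
    g <- as.numeric(2 * crossprod(b$J,
                                  config$weights * (b$pred - config$targets)))
    if (config$risk_weight > 0)
      g <- g + config$risk_weight * risk_grad(u, config$interaction_risk)
    loss <- multi_objective_loss(b$pred, u, config)
    if (constrained) {
      Cu <- risk(u, config$interaction_risk)
      if (Cu > config$risk_threshold) {
        g <- g + config$penalty * risk_grad(u, config$interaction_risk)
        loss <- loss + config$penalty * (Cu - config$risk_threshold)
      }
    }
  }
  if (any(!is.finite(g)))
    stop("non-finite intervention gradient", call. = FALSE)
  list(grad = g, loss = loss, pred = b$pred)
}

#' One gradient update of an intervention
#'
#' `u' = u - eta * grad_u L`, where `L` is the feedback loss
#' (squared deviation of the prediction from the observation) or the
#' multi-objective loss. The sensitivity of the prediction to `u` is
#' computed analytically for gland-network and forecaster predictors and by
#' central finite differences for plain functions.
#'
#' @param u current intervention vector.
#' @param predictor a [gland_network()], forecaster, or `function(h, u)`
#'   returning a prediction.
#' @param observed observed hormone vector.
#' @param config a [control_config()].
#' @param objective `"feedback"` or `"multi"`.
#' @param eta learning rate (defaults to `config$intervention_lr`).
#' @return updated intervention vector (clamped to `[0, u_max]` when
#'   configured).
#' @export
update_intervention <- function(u, predictor, observed, config,
                                objective = c("multi", "feedback"),
                                eta = config$intervention_lr) {
  objective <- match.arg(objective)
  pf <- as_predictor(predictor, dt = config$control_dt)
  g <- intervention_gradient(u, pf, observed, config, objective)
  clamp_u(u - eta * g$grad, config)
}

clamp_u <- function(u, config) {
  if (is.finite(config$u_max)) pmin(pmax(u, 0), config$u_max) else u
}

# Inner optimization of one control step: gradient descent with backtracking
# line search on the penalty-constrained objective, starting from the
# incumbent u. Backtracking keeps the descent monotone even when the large
# constraint penalty makes the landscape stiff near the feasibility kink.
optimize_intervention <- function(u, pred_fns, observed, config, eta) {
  cur <- intervention_gradient(u, pred_fns, observed, config, "multi",
                               constrained = TRUE)
  for (it in seq_len(config$max_iters)) {
    step <- eta
    moved <- FALSE
    for (bt in 1:40) {
      cand <- clamp_u(u - step * cur$grad, config)
      nxt <- intervention_gradient(cand, pred_fns, observed, config,
                                   "multi", constrained = TRUE)
      if (nxt$loss <= cur$loss) {
        if (sqrt(sum((cand - u)^2)) < config$convergence_tol) {
          u <- cand; cur <- nxt
          return(list(u = u, loss = cur$loss))
        }
        u <- cand; cur <- nxt; moved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!moved) break
  }
  list(u = u, loss = cur$loss)
}

#' Run the adaptive closed-loop regulation strategy
#'
#' Per control step: observe the plant; predict the next state under the
#' *current* intervention; compute the deviation of the previous prediction
#' from the new observation (and the stability index); optimize the
#' intervention by penalty-constrained gradient descent on the
#' multi-objective loss; decay the learning rate with the current total
#' deviation; optionally refresh the Bayesian patient posterior from the
#' observed transitions (the predictor then uses the posterior-mean
#' parameters); apply the updated intervention to the plant and log
#' everything.
#'
#' @param plant the true system: a [gland_network()].
#' @param config a [control_config()].
#' @param h0 initial plant state.
#' @param horizon number of control steps.
#' @param predictor prediction model used by the controller; defaults to the
#'   plant itself (an exact model). May be a [gland_network()], a
#'   forecaster, or a function.
#' @param u0 initial intervention (default zero).
#' @param posterior optional [patient_posterior()]; when supplied together
#'   with `param_spec` the posterior is updated from observed transitions
#'   every `update_posterior_every` steps and the predictor is rebuilt from
#'   the posterior mean.
#' @param param_spec parameter layout for the posterior, see
#'   [update_posterior()].
#' @param update_posterior_every posterior refresh interval in steps (0 =
#'   never).
#' @param obs_noise_sd Gaussian measurement noise added to plant
#'   observations (default 0).
#' @param seed seed for the measurement noise.
#' @return an object of class `"regulation_log"`: a data frame with one row
#'   per step (intervention, observed and predicted states, feedback loss,
#'   stability index, total deviation `D`, learning rate, constraint value
#'   `C(u)`, convergence flag), plus attributes `posterior` and `config`.
#' @export
closed_loop_run <- function(plant, config, h0, horizon,
                            predictor = NULL, u0 = NULL, posterior = NULL,
                            param_spec = NULL,
                            update_posterior_every = 0L,
                            obs_noise_sd = 0, seed = 1L) {
  stopifnot(inherits(plant, "gland_network"))
  N <- n_glands(plant)
  if (length(config$targets) != N)
    stop("config targets must match the plant dimension", call. = FALSE)
  if (is.null(u0)) u0 <- numeric(N)
  predictor_obj <- if (is.null(predictor)) plant else predictor
  pf <- as_predictor(predictor_obj, dt = config$control_dt)
  u <- u0
  eta <- config$intervention_lr
  h <- as.numeric(h0)
  pred_prev <- NULL
  dev_prev <- NULL
  rows <- vector("list", horizon)
  transitions <- list()
  with_local_seed(seed, {
    for (step in seq_len(horizon)) {
      hobs <- h
      if (obs_noise_sd > 0)
        hobs <- pmax(h + stats::rnorm(N, sd = obs_noise_sd), 0)
      dev <- if (is.null(pred_prev)) rep(NA_real_, N)
             else deviation(pred_prev, hobs)
      converged <- FALSE
      si <- NA_real_
      if (!is.null(dev_prev)) {
        if (sqrt(sum(dev_prev^2)) == 0) converged <- TRUE
        else si <- stability_index(dev, dev_prev)
      }
      # predict next state under the current (pre-update) intervention
      pred_under_current <- pf$predict(hobs, u)
      # optimize the intervention
      opt <- optimize_intervention(u, pf, hobs, config, eta)
      u_new <- opt$u
      D <- total_deviation(hobs, config$targets)
      fl <- if (all(is.finite(dev))) feedback_loss(dev) else NA_real_
      Cu <- risk(u_new, config$interaction_risk)
      rows[[step]] <- data.frame(
        iter = step, t(stats::setNames(u_new, paste0("u_", plant$gland_names))),
        t(stats::setNames(hobs, paste0("hobs_", plant$gland_names))),
        t(stats::setNames(pred_under_current,
                          paste0("hpred_", plant$gland_names))),
        feedback_loss = fl, stability_index = si, D = D, eta = eta,
        C_u = Cu, converged = converged)
      eta <- adapt_learning_rate(eta, D, config$decay)
      # posterior refresh from accumulated transitions
      if (!is.null(posterior) && update_posterior_every > 0L &&
          step %% update_posterior_every == 0L && length(transitions) > 0L) {
        posterior <- update_posterior(
          posterior, transitions,
          model = list(type = "transitions", network = plant,
                       param_spec = param_spec, dt = config$control_dt))
        pred_net <- apply_patient_params(plant, param_spec, posterior$mean)
        pf <- as_predictor(pred_net, dt = config$control_dt)
      }
      # apply the updated intervention to the plant
      h_next <- plant_step_with_sensitivity(plant, h, u_new,
                                            config$control_dt)$h
      h_next <- pmax(h_next, 0)
      transitions[[length(transitions) + 1L]] <-
        list(h = hobs, u = u_new, h_next = h_next)
      pred_prev <- pred_under_current
      dev_prev <- dev
      if (any(is.na(dev_prev))) dev_prev <- NULL
      u <- u_new
      h <- h_next
    }
  })
  log <- do.call(rbind, rows)
  attr(log, "posterior") <- posterior
  attr(log, "config") <- config
  class(log) <- c("regulation_log", class(log))
  log
}

#' @rdname closed_loop_run
#' @param ... passed to [closed_loop_run()].
#' @export
regulate <- function(plant, config, h0, horizon, ...) {
  closed_loop_run(plant, config, h0, horizon, ...)
}

#' @export
print.regulation_log <- function(x, ...) {
  cat("Closed-loop regulation log:", nrow(x), "steps\n")
  cat(sprintf("  total deviation D: %.6g -> %.6g\n", x$D[1],
              x$D[nrow(x)]))
  cat(sprintf("  final learning rate: %.4g; max C(u): %.4g\n",
              x$eta[nrow(x)], max(x$C_u)))
  invisible(x)
}

#' @export
plot.regulation_log <- function(x, ...) {
  graphics::plot(x$iter, x$D, type = "l", log = "y", xlab = "step",
                 ylab = "total deviation D", ...)
  invisible(x)
}
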