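#' Patient-parameter posterior
#'
#' Gaussian distributional state over patient-specific physiological
#' parameters (degradation rates, coupling strengths). Carries the current
#' mean and covariance, the prior they started from, and the observation
#' noise standard deviation of the measurement model.
#'
#' @param par_names parameter names.
#' @param mean current mean vector.
#' @param cov current covariance matrix (symmetric positive definite).
#' @param noise_sd observation-noise standard deviation (`> 0`).
#' @param prior_mean,prior_cov the prior (default: the current state).
#' @return an object of class `"patient_posterior"`.
#' @export
patient_posterior <- function(par_names, mean, cov, noise_sd,
                              prior_mean = mean, prior_cov = cov) {
  mean <- as.numeric(mean)
  P <- length(mean)
  if (!is.matrix(cov)) cov <- diag(as.numeric(cov), P)
  check_spd(cov)
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  structure(list(par_names = as.character(par_names), mean = mean,
                 cov = cov, noise_sd = noise_sd,
                 prior_mean = as.numeric(prior_mean),
                 prior_cov = if (is.matrix(prior_cov)) prior_cov else
                   diag(as.numeric(prior_cov), P)),
            class = "patient_posterior")
}

check_spd <- function(S) {
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8)) ||
      any(eigen(S, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("covariance must be symmetric positive definite", call. = FALSE)
  invisible(S)
}

#' @export
print.patient_posterior <- function(x, ...) {
  cat("Gaussian patient-parameter posterior\n")
  print(data.frame(parameter = x$par_names, mean = x$mean,
                   sd = sqrt(diag(x$cov))))
  invisible(x)
}

# Rebuild a network with patient parameters substituted according to
# param_spec (same layout as simulate_param_sensitivity).
apply_patient_params <- function(network, param_spec, values) {
  for (p in seq_along(param_spec)) {
    ps <- param_spec[[p]]
    if (ps$kind == "degradation")
      network$degradation[ps$i] <- max(values[p], 0)
    else network$coupling[ps$i, ps$j] <- values[p]
  }
  network
}

#' Bayesian update of patient parameters
#'
#' Updates a Gaussian [patient_posterior()] from observed data. Three
#' observation models are supported through `model$type`:
#'
#' * `"direct"`: linear-Gaussian observations `y = X theta + e`; the exact
#'   conjugate posterior is returned (`model$X` design matrix, `y` from
#'   `observations`).
#' * `"trajectory"`: `observations` is a [hormone_trajectory()] measured
#'   with Gaussian noise; the predicted trajectory is simulated from
#'   `model$network` with the candidate parameters substituted
#'   (`model$param_spec`) from the known initial state `model$h0`. The
#'   posterior mode is found by gradient ascent on the log posterior with
#'   analytic gradients via forward parameter-sensitivities through the RK4
#'   integrator, and the covariance is the Laplace (Gauss-Newton)
#'   approximation at the mode.
#' * `"transitions"`: `observations` is a list of one-step transitions
#'   `list(h, u, h_next)` under constant intervention over `model$dt`; same
#'   gradient-ascent/Laplace machinery on the one-step map.
#'
#' With empty observations the posterior is returned unchanged (Bayes with
#' no data).
#'
#' @param posterior a [patient_posterior()].
#' @param observations data as described above.
#' @param model observation-model description (list with `type` and
#'   type-specific fields).
#' @param max_iters,tol gradient-ascent controls for the non-conjugate path.
#' @return the updated [patient_posterior()].
#' @export
update_posterior <- function(posterior, observations, model,
                             max_iters = 200L, tol = 1e-10) {
  stopifnot(inherits(posterior, "patient_posterior"))
  if (is.null(observations) || length(observations) == 0L)
    return(posterior)
  if (model$type == "direct")
    return(conjugate_update(posterior, observations, model$X))
  if (model$type == "trajectory") {
    pred <- function(theta) trajectory_predictions(theta, model)
    y <- as.numeric(observations$states[-1L, , drop = FALSE])
  } else if (model$type == "transitions") {
    pred <- function(theta) transition_predictions(theta, model,
                                                   observations)
    y <- unlist(lapply(observations, function(tr) as.numeric(tr$h_next)),
                use.names = FALSE)
  } else stop("unknown observation model type", call. = FALSE)
  laplace_update(posterior, y, pred, max_iters, tol)
}

conjugate_update <- function(posterior, y, X) {
  y <- as.numeric(y)
  if (is.null(X)) X <- matrix(1, length(y), length(posterior$mean))
  X <- as.matrix(X)
  prec0 <- solve(posterior$cov)
  prec <- prec0 + crossprod(X) / posterior$noise_sd^2
  cov <- solve(prec)
  cov <- (cov + t(cov)) / 2
  mean <- as.numeric(cov %*% (prec0 %*% posterior$mean +
                              crossprod(X, y) / posterior$noise_sd^2))
  out <- posterior
  out$mean <- mean
  out$cov <- check_spd(cov)
  out
}

# Predictions + Jacobian for the whole-trajectory model. Returns list(mu, J)
# with mu the vectorized predicted states (rows 2..T) and J the nobs x P
# Jacobian from forward sensitivities.
trajectory_predictions <- function(theta, model) {
  net <- apply_patient_params(model$network, model$param_spec, theta)
  sim <- simulate_param_sensitivity(net, model$h0, model$horizon,
                                    model$step, model$param_spec,
                                    schedule = model$schedule)
  keep <- -1L
  mu <- as.numeric(sim$states[keep, , drop = FALSE])
  P <- length(theta)
  J <- matrix(0, length(mu), P)
  for (p in seq_len(P))
    J[, p] <- as.numeric(sim$sens[keep, , p])
  list(mu = mu, J = J)
}

# Predictions + Jacobian for the one-step transition model.
transition_predictions <- function(theta, model, transitions) {
  net <- apply_patient_params(model$network, model$param_spec, theta)
  N <- length(transitions[[1L]]$h)
  P <- length(theta)
  mu <- matrix(0, length(transitions), N)
  J <- matrix(0, length(transitions) * N, P)
  for (k in seq_along(transitions)) {
    tr <- transitions[[k]]
    sim <- simulate_param_sensitivity(net, tr$h, model$dt, model$dt / 10,
                                      model$param_spec, u_const = tr$u)
    last <- nrow(sim$states)
    mu[k, ] <- sim$states[last, ]
    for (p in seq_len(P))
      J[(k - 1L) * N + seq_len(N), p] <- sim$sens[last, , p]
  }
  list(mu = as.numeric(t(mu)), J = J)
}

# Gradient ascent on the Gaussian log posterior with backtracking, followed
# by a Laplace (Gauss-Newton) covariance at the mode.
laplace_update <- function(posterior, y, pred, max_iters, tol) {
  prec0 <- solve(posterior$prior_cov)
  s2 <- posterior$noise_sd^2
  logpost <- function(theta, pr) {
    r <- y - pr$mu
    -sum(r^2) / (2 * s2) -
      0.5 * as.numeric(t(theta - posterior$prior_mean) %*% prec0 %*%
                         (theta - posterior$prior_mean))
  }
  theta <- posterior$mean
  pr <- pred(theta)
  lp <- logpost(theta, pr)
  step0 <- 0.1
  for (it in seq_len(max_iters)) {
    r <- y - pr$mu
    g <- as.numeric(crossprod(pr$J, r)) / s2 -
      as.numeric(prec0 %*% (theta - posterior$prior_mean))
    if (any(!is.finite(g)))
      stop("non-finite log-posterior gradient", call. = FALSE)
    # Gauss-Newton preconditioning keeps the ascent well-scaled
    Hgn <- crossprod(pr$J) / s2 + prec0
    dir <- as.numeric(solve(Hgn, g))
    step <- 1
    improved <- FALSE
    for (bt in 1:30) {
      cand <- theta + step * dir
      prc <- pred(cand)
      lpc <- logpost(cand, prc)
      if (is.finite(lpc) && lpc >= lp) {
        improved <- TRUE
        delta <- sqrt(sum((cand - theta)^2))
        theta <- cand; pr <- prc; lp <- lpc
        break
      }
      step <- step / 2
    }
    if (!improved || delta < tol) break
  }
  Hgn <- crossprod(pr$J) / s2 + prec0
  cov <- solve(Hgn)
  cov <- (cov + t(cov)) / 2
  out <- posterior
  out$mean <- theta
  out$cov <- tryCatch(check_spd(cov),
                      error = function(e)
                        stop("posterior covariance lost positive ",
                             "definiteness after update", call. = FALSE))
  out
}
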