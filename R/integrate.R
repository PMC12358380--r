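#' Simulate a gland network
#'
#' Integrates the gland-network dynamics with a fixed-step classical
#' fourth-order Runge-Kutta scheme, sampling the solution every `step` time
#' units. Concentrations are clamped at zero from below after each step,
#' enforcing the physiological constraint \eqn{h_i(t) \ge 0}.
#'
#' @param network a [gland_network()].
#' @param h0 non-negative initial concentration vector of length `N`.
#' @param horizon total integration time (`>= step`).
#' @param step integration/output step (`> 0`), default 0.01.
#' @param schedule optional [intervention_schedule()] supplying `u(t)`.
#' @param t0 start time (default 0).
#' @return a [hormone_trajectory()] whose first row equals `h0`.
#' @examples
#' net <- gland_network("a", matrix(0, 1, 1), degradation = 1)
#' traj <- simulate_network(net, h0 = 1, horizon = 1, step = 0.01)
#' traj$states[nrow(traj$states), ] # ~ exp(-1)
#' @export
simulate_network <- function(network, h0, horizon, step = 0.01,
                             schedule = NULL, t0 = 0) {
  N <- n_glands(network)
  h0 <- as.numeric(h0)
  if (length(h0) != N || any(!is.finite(h0)) || any(h0 < 0))
    stop("h0 must be a finite non-negative vector of length ", N,
         call. = FALSE)
  if (!is.numeric(step) || step <= 0) stop("step must be > 0", call. = FALSE)
  if (horizon < step) stop("horizon must be >= step", call. = FALSE)

  nsteps <- as.integer(round(horizon / step))
  times <- t0 + step * (0:nsteps)
  states <- matrix(0, nsteps + 1L, N)
  inputs <- matrix(0, nsteps + 1L, N)
  colnames(states) <- colnames(inputs) <- network$gland_names
  h <- h0
  states[1L, ] <- h
  inputs[1L, ] <- stimulus_at(schedule, times[1L], N)
  guard <- 1e8
  for (k in seq_len(nsteps)) {
    t <- times[k]
    h <- rk4_step(network, h, t, step, schedule)
    h <- pmax(h, 0)
    if (any(!is.finite(h)) || max(abs(h)) > guard)
      stop(sprintf("integration diverged at t = %g (|h| exceeded %g)",
                   t + step, guard), call. = FALSE)
    states[k + 1L, ] <- h
    inputs[k + 1L, ] <- stimulus_at(schedule, times[k + 1L], N)
  }
  hormone_trajectory(times, states, inputs, network$gland_names)
}

# One classical RK4 step from time t to t + dt.
rk4_step <- function(network, h, t, dt, schedule) {
  N <- length(h)
  u1 <- stimulus_at(schedule, t, N)
  u2 <- stimulus_at(schedule, t + dt / 2, N)
  u4 <- stimulus_at(schedule, t + dt, N)
  k1 <- rates_raw(network, h, u1)
  k2 <- rates_raw(network, h + dt / 2 * k1, u2)
  k3 <- rates_raw(network, h + dt / 2 * k2, u2)
  k4 <- rates_raw(network, h + dt * k3, u4)
  h + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

# One-step transition map under a CONSTANT stimulus u over [0, dt], together
# with the sensitivity matrix S = d h(dt) / d u (N x N), propagated in
# forward mode through the same RK4 stages using the analytic state Jacobian:
#   dS/dt = J(h(t)) S + I.
# Used by the controller as the differentiable plant predictor. `substeps`
# subdivides dt for accuracy.
plant_step_with_sensitivity <- function(network, h, u, dt, substeps = 10L) {
  N <- length(h)
  S <- matrix(0, N, N)
  sdt <- dt / substeps
  I <- diag(N)
  for (s in seq_len(substeps)) {
    f <- function(hh, SS) {
      J <- network_jacobian(network, hh)
      list(dh = rates_raw(network, hh, u), dS = J %*% SS + I)
    }
    k1 <- f(h, S)
    k2 <- f(h + sdt / 2 * k1$dh, S + sdt / 2 * k1$dS)
    k3 <- f(h + sdt / 2 * k2$dh, S + sdt / 2 * k2$dS)
    k4 <- f(h + sdt * k3$dh, S + sdt * k3$dS)
    h <- h + sdt / 6 * (k1$dh + 2 * k2$dh + 2 * k3$dh + k4$dh)
    S <- S + sdt / 6 * (k1$dS + 2 * k2$dS + 2 * k3$dS + k4$dS)
  }
  list(h = h, S = S)
}

# Forward sensitivities of a simulated trajectory with respect to selected
# physiological parameters (degradation rates and coupling strengths).
# `param_spec` is a list of entries list(kind = "degradation", i = ...) or
# list(kind = "coupling", i = ..., j = ...). Returns the trajectory states
# (T x N, no clamping so the map stays smooth for inference) and the
# sensitivity array (T x N x P). Uses dF/dgamma_i = -h_i e_i and
# dF/dbeta_ij = g_ij(h_j) e_i, with the chain term J(h) S.
simulate_param_sensitivity <- function(network, h0, horizon, step,
                                       param_spec, schedule = NULL, t0 = 0,
                                       u_const = NULL) {
  N <- n_glands(network)
  P <- length(param_spec)
  nsteps <- as.integer(round(horizon / step))
  times <- t0 + step * (0:nsteps)
  states <- matrix(0, nsteps + 1L, N)
  sens <- array(0, c(nsteps + 1L, N, P))
  h <- as.numeric(h0)
  S <- matrix(0, N, P)
  states[1L, ] <- h

  dFdp <- function(hh) {
    out <- matrix(0, N, P)
    for (p in seq_len(P)) {
      ps <- param_spec[[p]]
      if (ps$kind == "degradation") {
        out[ps$i, p] <- -hh[ps$i]
      } else {
        r <- secretion_response(
          names(RESPONSE_CODES)[network$resp_type[ps$i, ps$j]],
          K = network$resp_K[ps$i, ps$j], n = network$resp_n[ps$i, ps$j])
        out[ps$i, p] <- response_value(r, hh[ps$j])
      }
    }
    out
  }
  for (k in seq_len(nsteps)) {
    t <- times[k]
    f <- function(hh, SS, tt) {
      u <- if (!is.null(u_const)) u_const else stimulus_at(schedule, tt, N)
      J <- network_jacobian(network, hh)
      list(dh = rates_raw(network, hh, u), dS = J %*% SS + dFdp(hh))
    }
    k1 <- f(h, S, t)
    k2 <- f(h + step / 2 * k1$dh, S + step / 2 * k1$dS, t + step / 2)
    k3 <- f(h + step / 2 * k2$dh, S + step / 2 * k2$dS, t + step / 2)
    k4 <- f(h + step * k3$dh, S + step * k3$dS, t + step)
    h <- h + step / 6 * (k1$dh + 2 * k2$dh + 2 * k3$dh + k4$dh)
    S <- S + step / 6 * (k1$dS + 2 * k2$dS + 2 * k3$dS + k4$dS)
    states[k + 1L, ] <- h
    sens[k + 1L, , ] <- S
  }
  list(times = times, states = states, sens = sens)
}
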