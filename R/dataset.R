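#' Synthetic-dataset specification
#'
#' Describes how a collection of hormone trajectories is drawn from a gland
#' network: initial concentrations are sampled uniformly per gland from
#' `init_ranges`, the network is integrated over `horizon` with output every
#' `step`, and i.i.d. Gaussian observation noise of standard deviation
#' `noise_sd` is added to the states (which are then clamped at zero).
#' Generation is fully determined by `seed`.
#'
#' @param n_trajectories number of trajectories (`>= 1`).
#' @param horizon integration horizon in time units.
#' @param step output interval (`> 0`).
#' @param init_ranges either a length-2 vector `c(lo, hi)` applied to every
#'   gland, or an `N x 2` matrix of per-gland sampling intervals for `h(0)`.
#' @param noise_sd observation-noise standard deviation (`>= 0`).
#' @param seed integer seed.
#' @return an object of class `"synthetic_dataset_spec"`.
#' @export
synthetic_dataset_spec <- function(n_trajectories, horizon = 6, step = 0.1,
                                   init_ranges = c(0.2, 2), noise_sd = 0.02,
                                   seed = 42L) {
  if (!is.numeric(n_trajectories) || n_trajectories < 1)
    stop("n_trajectories must be >= 1", call. = FALSE)
  if (step <= 0) stop("step must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  init_ranges <- if (is.matrix(init_ranges)) init_ranges else
    matrix(init_ranges, 1, 2)
  if (ncol(init_ranges) != 2 || nrow(init_ranges) == 0)
    stop("init_ranges must be c(lo, hi) or an N x 2 matrix", call. = FALSE)
  if (any(init_ranges[, 1] > init_ranges[, 2]) || any(init_ranges < 0))
    stop("init_ranges must satisfy 0 <= lo <= hi", call. = FALSE)
  structure(
    list(n_trajectories = as.integer(n_trajectories), horizon = horizon,
         step = step, init_ranges = init_ranges, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "synthetic_dataset_spec"
  )
}

#' Generate a synthetic trajectory dataset
#'
#' Draws `spec$n_trajectories` noisy hormone trajectories from `network`
#' according to a [synthetic_dataset_spec()]. With `noise_sd = 0` each
#' trajectory equals the deterministic [simulate_network()] output for its
#' sampled initial state.
#'
#' @param network a [gland_network()].
#' @param spec a [synthetic_dataset_spec()].
#' @param schedule optional [intervention_schedule()] applied to every
#'   trajectory (default: no stimulus).
#' @return a list of [hormone_trajectory()] objects.
#' @export
generate_dataset <- function(network, spec, schedule = NULL) {
  stopifnot(inherits(network, "gland_network"),
            inherits(spec, "synthetic_dataset_spec"))
  N <- n_glands(network)
  ranges <- spec$init_ranges
  if (nrow(ranges) == 1L) ranges <- ranges[rep(1L, N), , drop = FALSE]
  if (nrow(ranges) != N)
    stop("init_ranges must have one row per gland", call. = FALSE)

  with_local_seed(spec$seed, {
    lapply(seq_len(spec$n_trajectories), function(i) {
      h0 <- stats::runif(N, ranges[, 1], ranges[, 2])
      traj <- simulate_network(network, h0, spec$horizon, spec$step,
                               schedule = schedule)
      if (spec$noise_sd > 0) {
        noisy <- traj$states +
          matrix(stats::rnorm(length(traj$states), sd = spec$noise_sd),
                 nrow(traj$states))
        traj$states <- pmax(noisy, 0)
      }
      traj
    })
  })
}

#' Simulate trajectories from a gland network
#'
#' [stats::simulate()] method: draws `nsim` noisy trajectories from the
#' network, a convenience wrapper around [generate_dataset()].
#'
#' @param object a [gland_network()].
#' @param nsim number of trajectories.
#' @param seed integer seed.
#' @param horizon,step,init_ranges,noise_sd forwarded to
#'   [synthetic_dataset_spec()].
#' @param schedule optional [intervention_schedule()].
#' @param ... unused.
#' @return list of [hormone_trajectory()] objects.
#' @export
simulate.gland_network <- function(object, nsim = 1, seed = 42L,
                                   horizon = 6, step = 0.1,
                                   init_ranges = c(0.2, 2),
                                   noise_sd = 0.02, schedule = NULL, ...) {
  spec <- synthetic_dataset_spec(nsim, horizon = horizon, step = step,
                                 init_ranges = init_ranges,
                                 noise_sd = noise_sd, seed = seed)
  generate_dataset(object, spec, schedule = schedule)
}

# Evaluates `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
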