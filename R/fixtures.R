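#' Deterministic toy gland systems
#'
#' Small, fully reproducible gland networks (with matching dataset
#' specifications) used throughout examples and tests:
#'
#' * `"hpt_axis"`: the hypothalamic-pituitary-thyroid chain
#'   TRH -> TSH -> T3 with a single negative feedback edge T3 -> TRH of
#'   strength `k_TRH = 0.5`; stimulatory edges use saturating (sigmoid)
#'   secretion responses, the feedback edge acts linearly on TRH.
#' * `"linear_2g"`: a linear two-gland cascade (identity responses,
#'   couplings `beta[2,1] = 0.6`, degradations 0.8 and 0.5). Its
#'   linearization is strictly dissipative, so trajectory norms decay
#'   monotonically without input.
#' * `"random_3g"`: a seeded random three-gland network; positive edges use
#'   Hill responses (`K = 1`, `n = 2`), negative edges act linearly, and the
#'   draw is repeated deterministically until the linearization around the
#'   origin is stable.
#'
#' @param name one of `"hpt_axis"`, `"linear_2g"`, `"random_3g"`.
#' @param seed integer seed (affects `random_3g` and the dataset spec seed).
#' @return `list(network = <gland_network>, spec = <synthetic_dataset_spec>)`.
#' @export
fixture_suite <- function(name = c("hpt_axis", "linear_2g", "random_3g"),
                          seed = 42L) {
  name <- match.arg(name)
  seed <- as.integer(seed)
  if (name == "hpt_axis") {
    k_trh <- 0.5
    coupling <- rbind(c(0, 0, -k_trh),
                      c(0.8, 0, 0),
                      c(0, 0.9, 0))
    resp <- matrix("identity", 3, 3)
    resp[2, 1] <- "sigmoid"
    resp[3, 2] <- "sigmoid"
    net <- gland_network(c("TRH", "TSH", "T3"), coupling,
                         degradation = c(0.6, 0.7, 0.5), response = resp)
    spec <- synthetic_dataset_spec(50, horizon = 6, step = 0.1,
                                   init_ranges = c(0.2, 2),
                                   noise_sd = 0.02, seed = seed)
  } else if (name == "linear_2g") {
    net <- gland_network(c("A", "B"),
                         coupling = rbind(c(0, 0), c(0.6, 0)),
                         degradation = c(0.8, 0.5), response = "identity")
    spec <- synthetic_dataset_spec(50, horizon = 6, step = 0.1,
                                   init_ranges = c(0.2, 2),
                                   noise_sd = 0.02, seed = seed)
  } else {
    net <- with_local_seed(seed, {
      repeat {
        coupling <- matrix(0, 3, 3)
        off <- which(diag(3) == 0)
        coupling[off] <- stats::runif(6, -0.4, 0.6) *
          stats::rbinom(6, 1, 0.7)
        gamma <- stats::runif(3, 0.4, 0.9)
        resp <- matrix("identity", 3, 3)
        resp[coupling > 0] <- "hill"
        cand <- gland_network(c("g1", "g2", "g3"), coupling,
                              degradation = gamma, response = resp)
        # require a stable linearization at a reference state
        J <- network_jacobian(cand, rep(1, 3))
        if (max(Re(eigen(J, only.values = TRUE)$values)) < -0.05 &&
            sum(coupling != 0) >= 2)
          break
      }
      cand
    })
    spec <- synthetic_dataset_spec(200, horizon = 6, step = 0.1,
                                   init_ranges = c(0.2, 2),
                                   noise_sd = 0.02, seed = seed)
  }
  list(network = net, spec = spec)
}
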