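#' Construct an endocrine gland network
#'
#' A gland network is a directed graph of `N` glands. Edge `(i, j)` carries a
#' signed coupling strength `coupling[i, j]` (per unit time): positive entries
#' encode stimulation of gland `i` by hormone `j`, negative entries encode
#' negative feedback (e.g. the inhibitory effect of circulating T3 on
#' hypothalamic TRH secretion). Each gland degrades its own hormone at rate
#' `degradation[i] >= 0`, and each edge transduces the upstream concentration
#' through a secretion response \eqn{g_{ij}(\cdot)} (see
#' [secretion_response()]).
#'
#' The hormone state `h(t)` evolves as
#' \deqn{dh_i/dt = \sum_j \beta_{ij}\, g_{ij}(h_j) - \gamma_i h_i + u_i(t),}
#' where `u(t)` is an external stimulus (drug dose, environmental input)
#' aligned to gland indices.
#'
#' @param gland_names character vector of unique, non-empty gland names.
#' @param coupling `N x N` numeric matrix of signed coupling strengths
#'   `beta[i, j]` (effect of hormone `j` on gland `i`).
#' @param degradation numeric vector of `N` non-negative degradation rates.
#' @param response secretion response(s): a single string or
#'   [secretion_response()] object applied to every edge, a list of length `N`
#'   (one response per *source* gland), or an `N x N` list/character matrix of
#'   per-edge responses.
#' @param K,n optional scalars forwarded to [secretion_response()] when
#'   `response` is given as a character.
#' @return an object of class `"gland_network"`.
#' @examples
#' net <- gland_network(
#'   c("TRH", "TSH", "T3"),
#'   coupling = rbind(c(0, 0, -0.5), c(0.8, 0, 0), c(0, 0.9, 0)),
#'   degradation = c(0.6, 0.7, 0.5)
#' )
#' net
#' @export
gland_network <- function(gland_names, coupling, degradation,
                          response = "identity", K = 1, n = 2) {
  if (!is.character(gland_names) || length(gland_names) == 0L)
    stop("gland_names must be a non-empty character vector", call. = FALSE)
  if (anyDuplicated(gland_names) || any(!nzchar(gland_names)))
    stop("gland names must be unique and non-empty", call. = FALSE)
  N <- length(gland_names)
  coupling <- as.matrix(coupling)
  if (!is.numeric(coupling) || nrow(coupling) != N || ncol(coupling) != N)
    stop("coupling must be a ", N, " x ", N, " numeric matrix", call. = FALSE)
  if (any(!is.finite(coupling)))
    stop("coupling must be finite", call. = FALSE)
  degradation <- as.numeric(degradation)
  if (length(degradation) != N || any(!is.finite(degradation)))
    stop("degradation must be a finite numeric vector of length ", N,
         call. = FALSE)
  if (any(degradation < 0))
    stop("degradation rates must be non-negative", call. = FALSE)

  resp <- normalize_responses(response, N, K, n)
  dimnames(coupling) <- list(gland_names, gland_names)
  structure(
    list(gland_names = gland_names, coupling = coupling,
         degradation = degradation,
         resp_type = resp$type, resp_K = resp$K, resp_n = resp$n),
    class = "gland_network"
  )
}

# Accepts the polymorphic `response` argument and returns N x N matrices of
# type codes / K / n.
normalize_responses <- function(response, N, K = 1, n = 2) {
  as_resp <- function(x) {
    if (inherits(x, "secretion_response")) x
    else if (is.character(x) && length(x) == 1L) secretion_response(x, K, n)
    else stop("invalid secretion response specification", call. = FALSE)
  }
  type <- matrix(RESPONSE_CODES[["identity"]], N, N)
  Km <- matrix(1, N, N)
  nm <- matrix(1, N, N)
  set_cell <- function(i, j, r) {
    type[i, j] <<- RESPONSE_CODES[[r$type]]
    Km[i, j] <<- r$K
    nm[i, j] <<- r$n
  }
  if (is.matrix(response)) {
    if (nrow(response) != N || ncol(response) != N)
      stop("per-edge response matrix must be ", N, " x ", N, call. = FALSE)
    for (i in seq_len(N)) for (j in seq_len(N))
      set_cell(i, j, as_resp(response[[i, j]]))
  } else if (is.list(response) && !inherits(response, "secretion_response")) {
    if (length(response) != N)
      stop("per-source response list must have length ", N, call. = FALSE)
    for (j in seq_len(N)) {
      r <- as_resp(response[[j]])
      for (i in seq_len(N)) set_cell(i, j, r)
    }
  } else {
    r <- as_resp(response)
    for (i in seq_len(N)) for (j in seq_len(N)) set_cell(i, j, r)
  }
  list(type = type, K = Km, n = nm)
}

#' @export
print.gland_network <- function(x, ...) {
  N <- length(x$gland_names)
  cat("Endocrine gland network with", N, "glands:",
      paste(x$gland_names, collapse = ", "), "\n")
  cat("coupling (beta[i, j], effect of j on i):\n")
  print(round(x$coupling, 4))
  cat("degradation rates:",
      paste(sprintf("%s=%.3g", x$gland_names, x$degradation),
            collapse = ", "), "\n")
  types <- names(RESPONSE_CODES)[x$resp_type]
  cat("secretion responses:", paste(unique(types), collapse = ", "), "\n")
  invisible(x)
}

#' Number of glands in a network
#' @param network a [gland_network()].
#' @return integer count of glands.
#' @export
n_glands <- function(network) length(network$gland_names)

#' Hormone rate of change
#'
#' Evaluates the right-hand side of the gland-network dynamics
#' \eqn{dh_i/dt = \sum_j \beta_{ij} g_{ij}(h_j) - \gamma_i h_i + u_i}.
#' The map is linear in the stimulus `inputs`.
#'
#' @param network a [gland_network()].
#' @param state numeric hormone-concentration vector of length `N`.
#' @param inputs numeric stimulus vector of length `N` (defaults to zero).
#' @return numeric vector of length `N` of concentration rates.
#' @examples
#' net <- gland_network(c("a", "b"), rbind(c(0, -0.5), c(0, 0)), c(0, 0))
#' hormone_rates(net, c(1, 2)) # feedback only: c(-1, 0)
#' @export
hormone_rates <- function(network, state, inputs = NULL) {
  N <- n_glands(network)
  if (is.null(inputs)) inputs <- numeric(N)
  if (length(state) != N)
    stop("state must have length ", N, call. = FALSE)
  if (length(inputs) != N)
    stop("inputs must have length ", N, call. = FALSE)
  if (any(!is.finite(state)) || any(!is.finite(inputs)))
    stop("state and inputs must be finite", call. = FALSE)
  rates_raw(network, state, inputs)
}

# Internal fast path without contract checks (used inside the RK4 stages,
# where intermediate states may transiently dip below zero).
rates_raw <- function(network, state, inputs) {
  G <- edge_response_matrix(network$resp_type, network$resp_K,
                            network$resp_n, state)
  unname(rowSums(network$coupling * G)) - network$degradation * state +
    inputs
}

#' Jacobian of the hormone rates with respect to the state
#'
#' \eqn{\partial (dh_i/dt) / \partial h_k =
#'   \beta_{ik}\, g'_{ik}(h_k) - \gamma_i \delta_{ik}}.
#'
#' @inheritParams hormone_rates
#' @return an `N x N` Jacobian matrix.
#' @export
network_jacobian <- function(network, state) {
  Gp <- edge_response_matrix(network$resp_type, network$resp_K,
                             network$resp_n, state, deriv = TRUE)
  network$coupling * Gp - diag(network$degradation, n_glands(network))
}

# Binary adjacency induced by non-zero couplings, used by the graph stage of
# the forecaster. Edge j -> i whenever coupling[i, j] != 0; the attention
# convention is row i = receiving node.
network_adjacency <- function(network) {
  A <- (network$coupling != 0) * 1
  dimnames(A) <- dimnames(network$coupling)
  A
}
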