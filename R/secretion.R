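#' Secretion-response functions
#'
#' Registry of the shapes available for the per-edge secretion response
#' \eqn{g_j(\cdot)} that transduces an upstream hormone concentration into a
#' secretion drive on a downstream gland: `"identity"` (\eqn{g(h) = h}),
#' `"sigmoid"` (logistic, \eqn{g(h) = 1/(1+e^{-h})}) and `"hill"`
#' (\eqn{g(h) = h^n/(K^n + h^n)}, half-saturation `K > 0`, cooperativity
#' `n >= 1`).
#'
#' @param type one of `"identity"`, `"sigmoid"`, `"hill"`.
#' @param K half-saturation constant of the Hill response (ignored otherwise).
#' @param n Hill coefficient, `n >= 1` (ignored otherwise).
#' @return an object of class `"secretion_response"`.
#' @examples
#' g <- secretion_response("hill", K = 1, n = 2)
#' response_value(g, c(0, 1, 2))
#' @export
secretion_response <- function(type = c("identity", "sigmoid", "hill"),
                               K = 1, n = 2) {
  type <- match.arg(type)
  if (type == "hill") {
    if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K <= 0)
      stop("hill response requires K > 0", call. = FALSE)
    if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1)
      stop("hill response requires n >= 1", call. = FALSE)
  }
  structure(list(type = type, K = K, n = n), class = "secretion_response")
}

RESPONSE_CODES <- c(identity = 1L, sigmoid = 2L, hill = 3L)

#' @rdname secretion_response
#' @param resp a `secretion_response` object.
#' @param h numeric vector of concentrations.
#' @export
response_value <- function(resp, h) {
  switch(resp$type,
    identity = h,
    sigmoid = stats::plogis(h),
    hill = {
      hp <- pmax(h, 0) # Hill undefined for h < 0 (transient solver excursions)
      hp^resp$n / (resp$K^resp$n + hp^resp$n)
    }
  )
}

#' @rdname secretion_response
#' @export
response_deriv <- function(resp, h) {
  switch(resp$type,
    identity = rep(1, length(h)),
    sigmoid = {
      s <- stats::plogis(h)
      s * (1 - s)
    },
    hill = {
      hp <- pmax(h, 0)
      n <- resp$n
      K <- resp$K
      denom <- (K^n + hp^n)^2
      ifelse(hp == 0 & n > 1, 0, n * K^n * hp^(n - 1) / denom)
    }
  )
}

# Vectorized evaluation over an edge grid: type/K/n are N x N matrices, h a
# length-N vector indexed by the SOURCE gland (column j), so entry [i, j] is
# g_ij(h_j). Returns an N x N matrix.
edge_response_matrix <- function(type_codes, Kmat, nmat, h, deriv = FALSE) {
  N <- length(h)
  H <- matrix(h, N, N, byrow = TRUE) # column j carries h_j
  out <- H # identity value; overwritten below where needed
  if (deriv) out <- matrix(1, N, N)
  sig <- type_codes == RESPONSE_CODES[["sigmoid"]]
  if (any(sig)) {
    s <- stats::plogis(H[sig])
    out[sig] <- if (deriv) s * (1 - s) else s
  }
  hil <- type_codes == RESPONSE_CODES[["hill"]]
  if (any(hil)) {
    hp <- pmax(H[hil], 0)
    K <- Kmat[hil]
    n <- nmat[hil]
    if (deriv) {
      v <- n * K^n * hp^(n - 1) / (K^n + hp^n)^2
      v[hp == 0 & n > 1] <- 0
      out[hil] <- v
    } else {
      out[hil] <- hp^n / (K^n + hp^n)
    }
  }
  out
}
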