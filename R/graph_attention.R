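#' Adjacency structure for the graph stage
#'
#' Wraps a binary or weighted adjacency matrix `A` (entry `[i, j]` non-zero
#' when gland `j` influences gland `i`) together with the self-loop
#' convention. Self-loops can be inserted into the neighbourhood *before* the
#' attention softmax (so the self coefficient is itself softmax-normalized,
#' the default) or added *after* attention with unit weight; `"none"` leaves
#' the adjacency untouched.
#'
#' @param base square adjacency matrix.
#' @param self_loops one of `"before"`, `"after"`, `"none"`.
#' @return an object of class `"adjacency_structure"`.
#' @export
adjacency_structure <- function(base,
                                self_loops = c("before", "after", "none")) {
  self_loops <- match.arg(self_loops)
  base <- as.matrix(base)
  if (nrow(base) != ncol(base))
    stop("adjacency must be square", call. = FALSE)
  structure(list(base = base, self_loops = self_loops,
                 support = (base != 0)),
            class = "adjacency_structure")
}

# Neighbourhood support over which attention is normalized.
attention_support <- function(adjacency) {
  sup <- adjacency$support
  if (adjacency$self_loops == "before") diag(sup) <- TRUE
  sup
}

#' Graph-attention parameters
#'
#' One linear transform `W` (`d_in x d_out`) and one attention vector `a`
#' (length `2 * d_out`) per layer, plus the LeakyReLU negative slope used in
#' the attention scores and the nonlinearity applied to layer outputs.
#'
#' @param layers list of `list(W = <d_in x d_out matrix>, a = <2*d_out vector>)`.
#' @param leaky_slope LeakyReLU negative slope in `(0, 1)` (default 0.2).
#' @param activation `"relu"` or `"tanh"`.
#' @return an object of class `"graph_attention_params"`.
#' @export
graph_attention_params <- function(layers, leaky_slope = 0.2,
                                   activation = c("relu", "tanh")) {
  activation <- match.arg(activation)
  if (!is.list(layers) || length(layers) < 1L)
    stop("at least one layer is required", call. = FALSE)
  if (leaky_slope <= 0 || leaky_slope >= 1)
    stop("leaky_slope must lie in (0, 1)", call. = FALSE)
  din <- NULL
  for (l in seq_along(layers)) {
    W <- layers[[l]]$W
    a <- layers[[l]]$a
    if (!is.matrix(W) || length(a) != 2L * ncol(W))
      stop("layer ", l, ": a must have length 2 * ncol(W)", call. = FALSE)
    if (!is.null(din) && nrow(W) != din)
      stop("layer ", l, ": input width ", nrow(W),
           " does not chain from previous output width ", din,
           call. = FALSE)
    din <- ncol(W)
  }
  structure(list(layers = layers, leaky_slope = leaky_slope,
                 activation = activation),
            class = "graph_attention_params")
}

act_fun <- function(x, activation) {
  if (activation == "relu") pmax(x, 0) else tanh(x)
}
act_deriv <- function(pre, activation) {
  if (activation == "relu") (pre > 0) * 1 else 1 - tanh(pre)^2
}
leaky_relu <- function(x, slope) ifelse(x > 0, x, slope * x)

#' Attention coefficients for one graph layer
#'
#' Computes the softmax-normalized attention matrix: the score of edge
#' `j -> i` is `LeakyReLU(a' [z_i || z_j])` with `z = node_states %*% W`, and
#' row `i` is normalized over the neighbourhood of `i` (including the
#' self-loop under the `"before"` convention). Entries off the neighbourhood
#' are zero; every non-empty row sums to one.
#'
#' @param node_states `N x d_in` matrix of node features.
#' @param adjacency an [adjacency_structure()].
#' @param params a [graph_attention_params()].
#' @param layer layer index.
#' @return `N x N` attention matrix.
#' @export
attention_coefficients <- function(node_states, adjacency, params,
                                   layer = 1L) {
  if (any(!is.finite(node_states)))
    stop("node states must be finite", call. = FALSE)
  lay <- params$layers[[layer]]
  Z <- node_states %*% lay$W
  attention_from_transformed(Z, adjacency, lay$a, params$leaky_slope)
}

# Attention on already-transformed features Z (N x d_out).
attention_from_transformed <- function(Z, adjacency, a, slope) {
  N <- nrow(Z)
  d <- ncol(Z)
  a1 <- a[seq_len(d)]
  a2 <- a[d + seq_len(d)]
  p <- as.numeric(Z %*% a1)
  q <- as.numeric(Z %*% a2)
  E <- leaky_relu(outer(p, q, "+"), slope)
  sup <- attention_support(adjacency)
  if (any(rowSums(sup) == 0))
    stop("isolated node(s) without self-loop: ",
         paste(which(rowSums(sup) == 0), collapse = ", "), call. = FALSE)
  W <- exp(E - apply(ifelse(sup, E, -Inf), 1L, max)) # row-wise stabilization
  W[!sup] <- 0
  W / rowSums(W)
}

#' One graph-attention layer
#'
#' Updates node states as
#' \eqn{h_i' = \sigma(W h_i + \sum_{j \in N(i)} \alpha_{ij} W h_j)}; in
#' matrix form `sigma((I + Alpha) %*% Z)` with `Z = H %*% W`.
#'
#' @inheritParams attention_coefficients
#' @return `N x d_out` matrix of updated node states.
#' @export
gnn_layer <- function(node_states, adjacency, params, layer = 1L) {
  lay <- params$layers[[layer]]
  if (ncol(node_states) != nrow(lay$W))
    stop("node states have width ", ncol(node_states),
         " but layer expects ", nrow(lay$W), call. = FALSE)
  Z <- node_states %*% lay$W
  Alpha <- attention_from_transformed(Z, adjacency, lay$a,
                                      params$leaky_slope)
  act_fun(Z + Alpha %*% Z, params$activation)
}

#' Row-wise L2 normalization of node states
#'
#' Rescales every non-zero row to unit Euclidean norm, preventing
#' amplification of the node representations across layers. Zero rows are
#' returned unchanged (the normalization is undefined at the origin).
#'
#' @param node_states numeric matrix.
#' @return matrix of the same shape; idempotent.
#' @export
normalize_states <- function(node_states) {
  nrm <- sqrt(rowSums(node_states^2))
  scale <- ifelse(nrm > 0, 1 / nrm, 1)
  node_states * scale
}

#' Full graph-stage forward pass
#'
#' Applies `gnn_layer` followed by [normalize_states()] for each of the `L`
#' layers in `params`, producing the hierarchical spatial representation
#' consumed by the recurrent stage.
#'
#' @inheritParams attention_coefficients
#' @param initial_states `N x d_0` matrix of input node features.
#' @return `N x d_L` matrix; every row has L2 norm 1 (or 0).
#' @export
gnn_forward <- function(initial_states, adjacency, params) {
  H <- initial_states
  for (l in seq_along(params$layers))
    H <- normalize_states(gnn_layer(H, adjacency, params, l))
  H
}

# Forward pass with cached intermediates for backpropagation. Returns the
# output plus, per layer, everything the backward pass needs.
gnn_forward_cached <- function(X, adjacency, params) {
  caches <- vector("list", length(params$layers))
  sup <- attention_support(adjacency)
  H <- X
  for (l in seq_along(params$layers)) {
    lay <- params$layers[[l]]
    d <- ncol(lay$W)
    a1 <- lay$a[seq_len(d)]
    a2 <- lay$a[d + seq_len(d)]
    Z <- H %*% lay$W
    p <- as.numeric(Z %*% a1)
    q <- as.numeric(Z %*% a2)
    Eraw <- outer(p, q, "+")
    E <- leaky_relu(Eraw, params$leaky_slope)
    Wexp <- exp(E - apply(ifelse(sup, E, -Inf), 1L, max))
    Wexp[!sup] <- 0
    Alpha <- Wexp / rowSums(Wexp)
    P <- Z + Alpha %*% Z
    A <- act_fun(P, params$activation)
    nrm <- sqrt(rowSums(A^2))
    scale <- ifelse(nrm > 0, 1 / nrm, 1)
    Hn <- A * scale
    caches[[l]] <- list(X = H, Z = Z, Eraw = Eraw, Alpha = Alpha, P = P,
                        A = A, scale = scale, nrm = nrm)
    H <- Hn
  }
  list(out = H, caches = caches, support = sup)
}

# Backward pass through the cached graph stage. dOut is the gradient w.r.t.
# the final normalized output. Returns gradients for every layer's W and a,
# and for the input X.
gnn_backward <- function(dOut, cache, params) {
  L <- length(params$layers)
  gW <- vector("list", L)
  ga <- vector("list", L)
  dH <- dOut
  sup <- cache$support
  for (l in rev(seq_len(L))) {
    cc <- cache$caches[[l]]
    lay <- params$layers[[l]]
    d <- ncol(lay$W)
    a1 <- lay$a[seq_len(d)]
    a2 <- lay$a[d + seq_len(d)]
    # normalize backward: y = A * scale; dA = scale * (dY - y * <y, dY>)
    y <- cc$A * cc$scale
    dot <- rowSums(y * dH)
    dA <- cc$scale * (dH - y * dot)
    zr <- cc$nrm == 0
    if (any(zr)) dA[zr, ] <- dH[zr, , drop = FALSE] # identity on zero rows
    # activation backward
    dP <- dA * act_deriv(cc$P, params$activation)
    # P = Z + Alpha Z
    dZ <- dP + crossprod(cc$Alpha, dP)
    dAlpha <- tcrossprod(dP, cc$Z) # dP %*% t(Z)
    # softmax backward per row, restricted to support
    rowdot <- rowSums(cc$Alpha * dAlpha)
    dE <- cc$Alpha * (dAlpha - rowdot)
    dE[!sup] <- 0
    # LeakyReLU backward
    dEraw <- dE * ifelse(cc$Eraw > 0, 1, params$leaky_slope)
    dp <- rowSums(dEraw)
    dq <- colSums(dEraw)
    ga[[l]] <- c(as.numeric(crossprod(cc$Z, dp)),
                 as.numeric(crossprod(cc$Z, dq)))
    dZ <- dZ + outer(dp, a1) + outer(dq, a2)
    gW[[l]] <- crossprod(cc$X, dZ)
    dH <- tcrossprod(dZ, lay$W) # dZ %*% t(W)
  }
  list(gW = gW, ga = ga, dX = dH)
}
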