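# Independent brute-force oracles and small builders shared across tests.
# Every oracle is written as plain loops over the defining sums, independent
# of the package's vectorized implementations.

# term-by-term evaluation of dh_i/dt = sum_j beta_ij g_ij(h_j) - gamma_i h_i + u_i
oracle_rates <- function(network, h, u = numeric(length(h))) {
  N <- length(h)
  types <- names(RESPONSE_CODES)[network$resp_type]
  dim(types) <- dim(network$resp_type)
  out <- numeric(N)
  for (i in seq_len(N)) {
    acc <- 0
    for (j in seq_len(N)) {
      g <- switch(types[i, j],
        identity = h[j],
        sigmoid = 1 / (1 + exp(-h[j])),
        hill = {
          K <- network$resp_K[i, j]; n <- network$resp_n[i, j]
          max(h[j], 0)^n / (K^n + max(h[j], 0)^n)
        })
      acc <- acc + network$coupling[i, j] * g
    }
    out[i] <- acc - network$degradation[i] * h[i] + u[i]
  }
  out
}

# direct softmax-attention evaluation: scores on transformed features
oracle_attention <- function(X, W, a, support, slope) {
  Z <- X %*% W
  N <- nrow(Z); d <- ncol(Z)
  A <- matrix(0, N, N)
  for (i in seq_len(N)) {
    nb <- which(support[i, ])
    e <- sapply(nb, function(j) {
      s <- sum(a * c(Z[i, ], Z[j, ]))
      if (s > 0) s else slope * s
    })
    w <- exp(e - max(e))
    A[i, nb] <- w / sum(w)
  }
  A
}

# scalar-loop LSTM step (vector inputs)
oracle_lstm <- function(x, hprev, cprev, p) {
  dh <- length(p$bf)
  sig <- function(z) 1 / (1 + exp(-z))
  hid <- cel <- numeric(dh)
  for (k in seq_len(dh)) {
    f <- sig(sum(p$Wf[k, ] * x) + sum(p$Uf[k, ] * hprev) + p$bf[k])
    i <- sig(sum(p$Wi[k, ] * x) + sum(p$Ui[k, ] * hprev) + p$bi[k])
    o <- sig(sum(p$Wo[k, ] * x) + sum(p$Uo[k, ] * hprev) + p$bo[k])
    ct <- tanh(sum(p$Wc[k, ] * x) + sum(p$Uc[k, ] * hprev) + p$bc[k])
    cel[k] <- f * cprev[k] + i * ct
    hid[k] <- o * tanh(cel[k])
  }
  list(hidden = hid, cell = cel)
}

# central finite differences of scalar f at x
fd_grad <- function(f, x, eps = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

# matrix-exponential solution of a LINEAR (identity-response) network with
# constant input u: h(t) = e^{At} h0 + A^{-1}(e^{At} - I) u, A = beta - diag(gamma)
oracle_linear_solution <- function(network, h0, t, u = NULL) {
  A <- network$coupling - diag(network$degradation, length(h0))
  E <- as.matrix(Matrix::expm(A * t))
  h <- as.numeric(E %*% h0)
  if (!is.null(u) && any(u != 0))
    h <- h + as.numeric(solve(A, (E - diag(length(h0))) %*% u))
  h
}

# deterministic random helpers
rmat <- function(nr, nc, scale = 0.5) matrix(stats::runif(nr * nc, -scale, scale), nr, nc)

random_linear_network <- function(N, seed) {
  set.seed(seed)
  repeat {
    beta <- rmat(N, N, 0.5); diag(beta) <- 0
    gamma <- stats::runif(N, 0.5, 1.2)
    A <- beta - diag(gamma, N)
    if (max(Re(eigen(A, only.values = TRUE)$values)) < -0.1)
      return(gland_network(paste0("g", seq_len(N)), beta, gamma))
  }
}

tiny_model <- function(N = 2, d = 3, layers = 1, d_encoder = 2,
                       d_hidden = 4, seed = 11, adjacency = NULL) {
  if (is.null(adjacency)) adjacency <- matrix(1, N, N) - diag(N)
  forecaster_init(adjacency, d = d, layers = layers,
                  d_encoder = d_encoder, d_hidden = d_hidden, seed = seed)
}

toy_traj <- function(T_ = 6, N = 2, seed = 1, with_inputs = TRUE) {
  set.seed(seed)
  states <- matrix(stats::runif(T_ * N, 0.1, 2), T_, N)
  inputs <- if (with_inputs) matrix(stats::runif(T_ * N, 0, 0.5), T_, N)
  hormone_trajectory(seq_len(T_) * 0.1, states, inputs)
}
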