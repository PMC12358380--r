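#' Recurrent (LSTM) gate parameters
#'
#' Gate parameters of the long short-term-memory update shared across glands:
#' input-to-hidden matrices `Wf, Wi, Wo, Wc` (`d_h x d_in`), hidden-to-hidden
#' matrices `Uf, Ui, Uo, Uc` (`d_h x d_h`) and biases `bf, bi, bo, bc`
#' (`d_h`).
#'
#' @param Wf,Wi,Wo,Wc input weight matrices.
#' @param Uf,Ui,Uo,Uc recurrent weight matrices.
#' @param bf,bi,bo,bc bias vectors.
#' @return an object of class `"recurrent_params"`.
#' @export
recurrent_params <- function(Wf, Wi, Wo, Wc, Uf, Ui, Uo, Uc,
                             bf, bi, bo, bc) {
  p <- list(Wf = Wf, Wi = Wi, Wo = Wo, Wc = Wc,
            Uf = Uf, Ui = Ui, Uo = Uo, Uc = Uc,
            bf = bf, bi = bi, bo = bo, bc = bc)
  dh <- nrow(Wf)
  din <- ncol(Wf)
  for (nm in c("Wi", "Wo", "Wc"))
    if (!all(dim(p[[nm]]) == c(dh, din)))
      stop(nm, " must be ", dh, " x ", din, call. = FALSE)
  for (nm in c("Uf", "Ui", "Uo", "Uc"))
    if (!all(dim(p[[nm]]) == c(dh, dh)))
      stop(nm, " must be ", dh, " x ", dh, call. = FALSE)
  for (nm in c("bf", "bi", "bo", "bc"))
    if (length(p[[nm]]) != dh)
      stop(nm, " must have length ", dh, call. = FALSE)
  structure(p, class = "recurrent_params")
}

#' One LSTM update step
#'
#' Standard gated recurrent update: logistic forget/input/output gates
#' `f, i, o`, candidate `c~ = tanh(.)`, cell
#' `c = f * c_prev + i * c~` and hidden state `s = o * tanh(c)`. Inputs may
#' be single vectors or matrices with one row per gland (the gland dimension
#' is treated as a batch; parameters are shared).
#'
#' @param input_state input vector (length `d_in`) or `N x d_in` matrix.
#' @param hidden_prev,cell_prev previous hidden/cell states (length `d_h`
#'   vectors or `N x d_h` matrices).
#' @param params a [recurrent_params()].
#' @return `list(hidden = , cell = )` with the same shape as the inputs.
#' @export
lstm_step <- function(input_state, hidden_prev, cell_prev, params) {
  vec_in <- !is.matrix(input_state)
  X <- if (vec_in) matrix(input_state, 1L) else input_state
  H <- if (!is.matrix(hidden_prev)) matrix(hidden_prev, 1L) else hidden_prev
  C <- if (!is.matrix(cell_prev)) matrix(cell_prev, 1L) else cell_prev
  if (any(!is.finite(X)) || any(!is.finite(H)) || any(!is.finite(C)))
    stop("lstm_step inputs must be finite", call. = FALSE)
  if (ncol(X) != ncol(params$Wf))
    stop("input width ", ncol(X), " does not match Wf (",
         ncol(params$Wf), " columns)", call. = FALSE)
  st <- lstm_step_cached(X, H, C, params)
  if (vec_in) list(hidden = as.numeric(st$Hn), cell = as.numeric(st$Cn))
  else list(hidden = st$Hn, cell = st$Cn)
}

sigmoid <- function(x) stats::plogis(x)

# Cached batched step used by both the public op and the training loop.
lstm_step_cached <- function(X, H, C, p) {
  lstm_step_pre(X, H, C,
                list(Wf = t(p$Wf), Wi = t(p$Wi), Wo = t(p$Wo),
                     Wc = t(p$Wc), Uf = t(p$Uf), Ui = t(p$Ui),
                     Uo = t(p$Uo), Uc = t(p$Uc),
                     bf = p$bf, bi = p$bi, bo = p$bo, bc = p$bc))
}

# Same step on pre-transposed weights (hot path of the training loop).
lstm_step_pre <- function(X, H, C, tp) {
  af <- X %*% tp$Wf + H %*% tp$Uf + rep(tp$bf, each = nrow(X))
  ai <- X %*% tp$Wi + H %*% tp$Ui + rep(tp$bi, each = nrow(X))
  ao <- X %*% tp$Wo + H %*% tp$Uo + rep(tp$bo, each = nrow(X))
  ac <- X %*% tp$Wc + H %*% tp$Uc + rep(tp$bc, each = nrow(X))
  f <- sigmoid(af)
  i <- sigmoid(ai)
  o <- sigmoid(ao)
  ct <- tanh(ac)
  Cn <- f * C + i * ct
  tc <- tanh(Cn)
  Hn <- o * tc
  list(X = X, Hprev = H, Cprev = C, f = f, i = i, o = o, ct = ct,
       Cn = Cn, tc = tc, Hn = Hn)
}

# Backward through one batched LSTM step. dH, dC are gradients w.r.t. the
# new hidden/cell states. Returns parameter gradients plus gradients for the
# inputs and the previous hidden/cell states.
lstm_backward <- function(dH, dC, st, p) {
  do <- dH * st$tc
  dCn <- dC + dH * st$o * (1 - st$tc^2)
  df <- dCn * st$Cprev
  di <- dCn * st$ct
  dct <- dCn * st$i
  dCprev <- dCn * st$f
  daf <- df * st$f * (1 - st$f)
  dai <- di * st$i * (1 - st$i)
  dao <- do * st$o * (1 - st$o)
  dac <- dct * (1 - st$ct^2)
  list(
    gWf = crossprod(daf, st$X), gUf = crossprod(daf, st$Hprev),
    gbf = colSums(daf),
    gWi = crossprod(dai, st$X), gUi = crossprod(dai, st$Hprev),
    gbi = colSums(dai),
    gWo = crossprod(dao, st$X), gUo = crossprod(dao, st$Hprev),
    gbo = colSums(dao),
    gWc = crossprod(dac, st$X), gUc = crossprod(dac, st$Hprev),
    gbc = colSums(dac),
    dX = daf %*% p$Wf + dai %*% p$Wi + dao %*% p$Wo + dac %*% p$Wc,
    dHprev = daf %*% p$Uf + dai %*% p$Ui + dao %*% p$Uo + dac %*% p$Uc,
    dCprev = dCprev
  )
}

#' Stimulus encoder parameters
#'
#' Two-layer perceptron encoding raw stimuli into the representation fed to
#' the recurrent stage: `u' = sigma(W2 sigma(W1 u + b1) + b2)`.
#'
#' @param W1,b1 first layer (`d_mid x d_u`, `d_mid`).
#' @param W2,b2 second layer (`d_enc x d_mid`, `d_enc`).
#' @param activation `"relu"` or `"tanh"`.
#' @return an object of class `"stimulus_encoder_params"`.
#' @export
stimulus_encoder_params <- function(W1, b1, W2, b2,
                                    activation = c("relu", "tanh")) {
  activation <- match.arg(activation)
  if (ncol(W2) != nrow(W1) || length(b1) != nrow(W1) ||
      length(b2) != nrow(W2))
    stop("encoder dimensions do not chain", call. = FALSE)
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                 activation = activation),
            class = "stimulus_encoder_params")
}

#' Encode an external stimulus
#'
#' @param inputs raw stimulus vector `u(t)` (length `d_u`).
#' @param params a [stimulus_encoder_params()].
#' @return encoded vector `u'(t)` of length `d_enc`.
#' @export
encode_stimulus <- function(inputs, params) {
  if (length(inputs) != ncol(params$W1))
    stop("stimulus has length ", length(inputs), " but encoder expects ",
         ncol(params$W1), call. = FALSE)
  a1 <- as.numeric(params$W1 %*% inputs + params$b1)
  h1 <- act_fun(a1, params$activation)
  a2 <- as.numeric(params$W2 %*% h1 + params$b2)
  act_fun(a2, params$activation)
}

encode_stimulus_cached <- function(u, p) {
  a1 <- as.numeric(p$W1 %*% u + p$b1)
  h1 <- act_fun(a1, p$activation)
  a2 <- as.numeric(p$W2 %*% h1 + p$b2)
  list(u = u, a1 = a1, h1 = h1, a2 = a2,
       out = act_fun(a2, p$activation))
}

encoder_backward <- function(dout, st, p) {
  da2 <- dout * act_deriv(st$a2, p$activation)
  dh1 <- as.numeric(crossprod(p$W2, da2))
  da1 <- dh1 * act_deriv(st$a1, p$activation)
  list(gW2 = outer(da2, st$h1), gb2 = da2,
       gW1 = outer(da1, st$u), gb1 = da1,
       du = as.numeric(crossprod(p$W1, da1)))
}
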