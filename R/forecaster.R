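#' Initialize a graph-attention recurrent forecaster
#'
#' Builds an untrained forecaster for `N` glands. Per time step the model
#' (i) lifts each scalar concentration into a `d`-dimensional node feature
#' through a learned linear map, (ii) runs `layers` graph-attention layers
#' with row-wise L2 normalization over the gland graph, (iii) encodes the
#' raw stimulus vector with a two-layer perceptron, (iv) updates one LSTM
#' per gland (weights shared across glands) on the concatenation
#' `[h_i(t) || graph feature_i || encoded stimulus]`, and (v) maps the
#' stacked hidden states through an affine readout to the predicted
#' concentrations at the next sample time.
#'
#' Weights are initialized with the Xavier (Glorot) uniform scheme; biases
#' start at zero.
#'
#' @param adjacency gland adjacency: a [gland_network()], an
#'   [adjacency_structure()], or a square matrix.
#' @param d node-feature width of the graph stage (default 16).
#' @param layers number of graph-attention layers (default 1).
#' @param d_encoder width of the encoded stimulus (default 8).
#' @param d_hidden LSTM hidden width (default 32).
#' @param activation nonlinearity of graph stage and encoder.
#' @param leaky_slope LeakyReLU slope of the attention scores.
#' @param self_loops self-loop convention, see [adjacency_structure()].
#' @param seed integer seed for the initialization draw.
#' @return an object of class `"forecaster_model"`.
#' @export
forecaster_init <- function(adjacency, d = 16L, layers = 1L,
                            d_encoder = 8L, d_hidden = 32L,
                            activation = c("relu", "tanh"),
                            leaky_slope = 0.2,
                            self_loops = c("before", "after", "none"),
                            seed = 42L) {
  activation <- match.arg(activation)
  self_loops <- match.arg(self_loops)
  gland_names <- NULL
  if (inherits(adjacency, "gland_network")) {
    gland_names <- adjacency$gland_names
    adjacency <- network_adjacency(adjacency)
  }
  if (!inherits(adjacency, "adjacency_structure"))
    adjacency <- adjacency_structure(adjacency, self_loops)
  N <- nrow(adjacency$base)
  if (is.null(gland_names)) gland_names <- rownames(adjacency$base)
  if (is.null(gland_names)) gland_names <- paste0("g", seq_len(N))

  xavier <- function(dout, din) {
    lim <- sqrt(6 / (din + dout))
    matrix(stats::runif(dout * din, -lim, lim), dout, din)
  }
  with_local_seed(seed, {
    glayers <- lapply(seq_len(layers), function(l)
      list(W = xavier(d, d), a = stats::runif(2 * d, -sqrt(6 / (2 * d + 1)),
                                              sqrt(6 / (2 * d + 1)))))
    din <- 1L + d + d_encoder
    par <- list(
      lift = list(w = stats::runif(d, -sqrt(6 / (1 + d)), sqrt(6 / (1 + d))),
                  b = numeric(d)),
      graph = list(layers = glayers),
      encoder = list(W1 = xavier(d_encoder, N), b1 = numeric(d_encoder),
                     W2 = xavier(d_encoder, d_encoder),
                     b2 = numeric(d_encoder)),
      lstm = list(Wf = xavier(d_hidden, din), Wi = xavier(d_hidden, din),
                  Wo = xavier(d_hidden, din), Wc = xavier(d_hidden, din),
                  Uf = xavier(d_hidden, d_hidden),
                  Ui = xavier(d_hidden, d_hidden),
                  Uo = xavier(d_hidden, d_hidden),
                  Uc = xavier(d_hidden, d_hidden),
                  bf = numeric(d_hidden), bi = numeric(d_hidden),
                  bo = numeric(d_hidden), bc = numeric(d_hidden)),
      readout = list(W3 = xavier(N, N * d_hidden), b3 = numeric(N))
    )
    structure(
      list(par = par, adjacency = adjacency, gland_names = gland_names,
           n_glands = N, d = d, layers = layers, d_encoder = d_encoder,
           d_hidden = d_hidden, activation = activation,
           leaky_slope = leaky_slope, self_loops = self_loops,
           seed = as.integer(seed)),
      class = "forecaster_model"
    )
  })
}

model_graph_params <- function(model) {
  graph_attention_params(model$par$graph$layers,
                         leaky_slope = model$leaky_slope,
                         activation = model$activation)
}

model_encoder_params <- function(model) {
  e <- model$par$encoder
  stimulus_encoder_params(e$W1, e$b1, e$W2, e$b2,
                          activation = model$activation)
}

#' Zero-initialized recurrent carry
#'
#' @param model a [forecaster_init()] model.
#' @return `list(hidden = , cell = )`, each an `N x d_hidden` zero matrix.
#' @export
zero_carry <- function(model) {
  list(hidden = matrix(0, model$n_glands, model$d_hidden),
       cell = matrix(0, model$n_glands, model$d_hidden))
}

# Precomputed per-forward context: validated parameter objects and
# pre-transposed LSTM weight matrices, built once per trajectory rather than
# once per time step.
forecaster_compile <- function(model) {
  lstm <- model$par$lstm
  list(gp = model_graph_params(model),
       ep = model_encoder_params(model),
       lstm_t = list(Wf = t(lstm$Wf), Wi = t(lstm$Wi), Wo = t(lstm$Wo),
                     Wc = t(lstm$Wc), Uf = t(lstm$Uf), Ui = t(lstm$Ui),
                     Uo = t(lstm$Uo), Uc = t(lstm$Uc),
                     bf = lstm$bf, bi = lstm$bi, bo = lstm$bo,
                     bc = lstm$bc))
}

# Core single-step forward with all intermediates cached (used by both the
# public op and the training engine).
forecaster_step_cached <- function(model, h, u, carry, drop_mask = NULL,
                                   ctx = forecaster_compile(model)) {
  par <- model$par
  N <- model$n_glands
  X0 <- outer(h, par$lift$w) + rep(par$lift$b, each = N)
  gfc <- gnn_forward_cached(X0, model$adjacency, ctx$gp)
  G <- gfc$out
  Gd <- if (is.null(drop_mask)) G else G * drop_mask
  enc <- encode_stimulus_cached(u, ctx$ep)
  Xin <- cbind(h, Gd, matrix(enc$out, N, model$d_encoder, byrow = TRUE))
  st <- lstm_step_pre(Xin, carry$hidden, carry$cell, ctx$lstm_t)
  svec <- as.numeric(t(st$Hn))
  pred <- as.numeric(par$readout$W3 %*% svec + par$readout$b3)
  list(pred = pred,
       carry = list(hidden = st$Hn, cell = st$Cn),
       h = h, u = u, X0 = X0, gfc = gfc, drop_mask = drop_mask,
       enc = enc, Xin = Xin, st = st, svec = svec)
}

# Backward through one cached step. dpred: gradient w.r.t. the prediction;
# dH, dC: gradients flowing back from the next step's carry. Returns nested
# parameter gradients (same shape as model$par) plus dHprev, dCprev, and
# gradients w.r.t. the raw inputs (d_state, d_u).
forecaster_step_backward <- function(model, cc, dpred, dH, dC,
                                     ctx = forecaster_compile(model)) {
  par <- model$par
  N <- model$n_glands
  dL <- model$d
  de <- model$d_encoder
  gW3 <- outer(dpred, cc$svec)
  gb3 <- dpred
  dsvec <- as.numeric(crossprod(par$readout$W3, dpred))
  dS <- matrix(dsvec, N, model$d_hidden, byrow = TRUE) + dH
  lb <- lstm_backward(dS, dC, cc$st, par$lstm)
  dXin <- lb$dX
  dh_in <- dXin[, 1L]
  dG <- dXin[, 1L + seq_len(dL), drop = FALSE]
  duenc <- colSums(dXin[, 1L + dL + seq_len(de), drop = FALSE])
  if (!is.null(cc$drop_mask)) dG <- dG * cc$drop_mask
  gb <- gnn_backward(dG, cc$gfc, ctx$gp)
  eb <- encoder_backward(duenc, cc$enc, ctx$ep)
  gw_lift <- as.numeric(crossprod(gb$dX, cc$h))
  gb_lift <- colSums(gb$dX)
  d_state <- dh_in + as.numeric(gb$dX %*% par$lift$w)
  grads <- list(
    lift = list(w = gw_lift, b = gb_lift),
    graph = list(layers = lapply(seq_along(gb$gW), function(l)
      list(W = gb$gW[[l]], a = gb$ga[[l]]))),
    encoder = list(W1 = eb$gW1, b1 = eb$gb1, W2 = eb$gW2, b2 = eb$gb2),
    lstm = list(Wf = lb$gWf, Wi = lb$gWi, Wo = lb$gWo, Wc = lb$gWc,
                Uf = lb$gUf, Ui = lb$gUi, Uo = lb$gUo, Uc = lb$gUc,
                bf = lb$gbf, bi = lb$gbi, bo = lb$gbo, bc = lb$gbc),
    readout = list(W3 = gW3, b3 = gb3)
  )
  list(grads = grads, dHprev = lb$dHprev, dCprev = lb$dCprev,
       d_state = d_state, d_u = eb$du)
}

#' One forward prediction step
#'
#' Runs the full per-step pipeline (graph lift and attention, stimulus
#' encoding, per-gland recurrent update, affine readout) and returns the
#' predicted concentrations for the next sample time together with the
#' updated recurrent carry. The function is pure: identical inputs and carry
#' give identical outputs.
#'
#' @param model a [forecaster_init()] model.
#' @param observed_state hormone concentration vector of length `N`.
#' @param inputs stimulus vector of length `N`.
#' @param carry recurrent state, see [zero_carry()].
#' @return `list(prediction = , carry = )`.
#' @export
forward_step <- function(model, observed_state, inputs = NULL,
                         carry = zero_carry(model)) {
  N <- model$n_glands
  if (is.null(inputs)) inputs <- numeric(N)
  if (length(observed_state) != N || length(inputs) != N)
    stop("state and inputs must have length ", N, call. = FALSE)
  cc <- forecaster_step_cached(model, as.numeric(observed_state),
                               as.numeric(inputs), carry)
  list(prediction = cc$pred, carry = cc$carry)
}

#' Mean squared prediction error
#'
#' `mean((observations - predictions)^2)` over all `T x N` entries; the
#' training objective of the forecaster.
#'
#' @param predictions,observations equal-shaped numeric matrices (or
#'   vectors).
#' @return non-negative scalar; symmetric in its arguments.
#' @export
mse_loss <- function(predictions, observations) {
  predictions <- as.matrix(predictions)
  observations <- as.matrix(observations)
  if (!all(dim(predictions) == dim(observations)))
    stop("predictions and observations must have the same shape",
         call. = FALSE)
  mean((predictions - observations)^2)
}

#' Closed-loop (autoregressive) forecast
#'
#' Rolls the forecaster forward `steps` steps: step `k` feeds the prediction
#' of step `k - 1` back in as the input state, while stimuli are read from
#' `schedule` on the time grid `t0 + (k - 1) * dt`. Predictions are clamped
#' at zero for the returned trajectory container.
#'
#' @param model a `forecaster_model` (or [endo_forecaster()] fit).
#' @param initial_state starting concentration vector.
#' @param schedule optional [intervention_schedule()].
#' @param steps number of forecast steps (`>= 1`).
#' @param dt sample interval of the forecast grid.
#' @param t0 start time.
#' @return a [hormone_trajectory()] with `steps + 1` rows (first row is the
#'   initial state).
#' @export
rollout <- function(model, initial_state, schedule = NULL, steps, dt = 0.1,
                    t0 = 0) {
  if (inherits(model, "endo_forecaster")) model <- model$model
  if (steps < 1) stop("steps must be >= 1", call. = FALSE)
  N <- model$n_glands
  h <- pmax(as.numeric(initial_state), 0)
  carry <- zero_carry(model)
  states <- matrix(0, steps + 1L, N)
  inputs <- matrix(0, steps + 1L, N)
  states[1L, ] <- h
  for (k in seq_len(steps)) {
    u <- stimulus_at(schedule, t0 + (k - 1) * dt, N)
    inputs[k, ] <- u
    fs <- forward_step(model, h, u, carry)
    carry <- fs$carry
    h <- pmax(fs$prediction, 0)
    states[k + 1L, ] <- h
  }
  inputs[steps + 1L, ] <- stimulus_at(schedule, t0 + steps * dt, N)
  hormone_trajectory(t0 + dt * (0:steps), states, inputs,
                     model$gland_names)
}
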