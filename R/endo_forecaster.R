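#' Fit a hormone-trajectory forecaster
#'
#' High-level fitting interface in the classic R modelling idiom: takes a
#' dataset of hormone trajectories and the gland graph, initializes a
#' graph-attention recurrent forecaster ([forecaster_init()]), trains it by
#' teacher forcing ([train_forecaster()]) and returns a classed fit with the
#' usual methods (`print`, `summary`, `coef`, `predict`, `residuals`,
#' `plot`).
#'
#' @param dataset list of [hormone_trajectory()] objects, e.g. from
#'   [generate_dataset()].
#' @param network a [gland_network()] (or adjacency matrix) defining the
#'   gland graph.
#' @param d,layers,d_encoder,d_hidden,activation,leaky_slope,self_loops
#'   architecture settings, see [forecaster_init()].
#' @param config a [training_config()].
#' @return an object of class `"endo_forecaster"`.
#' @examples
#' \donttest{
#' fx <- fixture_suite("linear_2g", seed = 1)
#' data <- generate_dataset(fx$network,
#'   synthetic_dataset_spec(20, horizon = 3, step = 0.1, seed = 1))
#' fit <- endo_forecaster(data, fx$network, d = 4, d_hidden = 8,
#'   d_encoder = 4, config = training_config(max_epochs = 5))
#' fit
#' }
#' @export
endo_forecaster <- function(dataset, network, d = 16L, layers = 1L,
                            d_encoder = 8L, d_hidden = 32L,
                            activation = "relu", leaky_slope = 0.2,
                            self_loops = "before",
                            config = training_config()) {
  model <- forecaster_init(network, d = d, layers = layers,
                           d_encoder = d_encoder, d_hidden = d_hidden,
                           activation = activation,
                           leaky_slope = leaky_slope,
                           self_loops = self_loops, seed = config$seed)
  tr <- train_forecaster(model, dataset, config)
  structure(
    list(model = tr$model, history = tr$history, split = tr$split,
         config = config, dataset = dataset, call = match.call()),
    class = "endo_forecaster"
  )
}

#' @export
print.endo_forecaster <- function(x, ...) {
  m <- x$model
  cat("Graph-attention recurrent hormone forecaster\n")
  cat(sprintf("  glands: %d (%s)\n", m$n_glands,
              paste(m$gland_names, collapse = ", ")))
  cat(sprintf("  graph width %d x %d layer(s), encoder %d, hidden %d\n",
              m$d, m$layers, m$d_encoder, m$d_hidden))
  if (nrow(x$history) > 0)
    cat(sprintf("  trained %d epoch(s); best validation MSE %.6g\n",
                nrow(x$history), min(x$history$val)))
  else cat("  untrained\n")
  invisible(x)
}

#' @export
summary.endo_forecaster <- function(object, ...) {
  test_mse <- if (length(object$split$test) > 0)
    mean(vapply(object$split$test, function(i)
      forecaster_traj_grad(object$model, object$dataset[[i]],
                           want_grad = FALSE)$loss, numeric(1)))
  else NA_real_
  out <- list(
    n_trajectories = length(object$dataset),
    split_sizes = lengths(object$split),
    epochs = nrow(object$history),
    final_train = if (nrow(object$history)) utils::tail(object$history$train, 1) else NA_real_,
    best_val = if (nrow(object$history)) min(object$history$val) else NA_real_,
    test_mse = test_mse,
    n_parameters = length(flatten_params(object$model$par))
  )
  class(out) <- "summary.endo_forecaster"
  out
}

#' @export
print.summary.endo_forecaster <- function(x, ...) {
  cat("Forecaster fit summary\n")
  cat(sprintf("  trajectories: %d (train/val/test = %s)\n",
              x$n_trajectories, paste(x$split_sizes, collapse = "/")))
  cat(sprintf("  parameters: %d; epochs: %d\n", x$n_parameters, x$epochs))
  cat(sprintf("  final train MSE: %.6g; best validation MSE: %.6g\n",
              x$final_train, x$best_val))
  if (is.finite(x$test_mse))
    cat(sprintf("  held-out test MSE: %.6g\n", x$test_mse))
  invisible(x)
}

#' @export
coef.endo_forecaster <- function(object, ...) object$model$par

#' Predict from a fitted forecaster
#'
#' `type = "onestep"` returns teacher-forced one-step-ahead predictions for
#' a supplied trajectory (a `(T-1) x N` matrix aligned with rows `2..T` of
#' the observations). `type = "rollout"` produces an autoregressive forecast
#' from an initial state via [rollout()].
#'
#' @param object an [endo_forecaster()] fit.
#' @param newdata a [hormone_trajectory()] (for `"onestep"`).
#' @param type `"onestep"` or `"rollout"`.
#' @param initial_state,schedule,steps,dt,t0 rollout arguments.
#' @param ... unused.
#' @export
predict.endo_forecaster <- function(object, newdata = NULL,
                                    type = c("onestep", "rollout"),
                                    initial_state = NULL, schedule = NULL,
                                    steps = 10L, dt = 0.1, t0 = 0, ...) {
  type <- match.arg(type)
  if (type == "rollout") {
    if (is.null(initial_state))
      stop("rollout prediction needs initial_state", call. = FALSE)
    return(rollout(object$model, initial_state, schedule, steps, dt, t0))
  }
  if (is.null(newdata))
    stop("one-step prediction needs a trajectory as newdata", call. = FALSE)
  res <- forecaster_traj_grad(object$model, newdata, want_grad = FALSE)
  preds <- res$preds
  colnames(preds) <- object$model$gland_names
  preds
}

#' @export
residuals.endo_forecaster <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    idx <- if (length(object$split$test) > 0) object$split$test else
      object$split$val
    newdata <- object$dataset[[idx[1L]]]
  }
  preds <- predict(object, newdata, type = "onestep")
  newdata$states[-1L, , drop = FALSE] - preds
}

#' @export
plot.endo_forecaster <- function(x, ...) {
  h <- x$history
  if (nrow(h) == 0) {
    warning("no training history to plot")
    return(invisible(x))
  }
  graphics::matplot(h$epoch, cbind(h$train, h$val), type = "l", lty = 1,
                    col = c("black", "red"), xlab = "epoch",
                    ylab = "MSE", log = "y", ...)
  graphics::legend("topright", legend = c("train", "validation"),
                   col = c("black", "red"), lty = 1, bty = "n")
  invisible(x)
}
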