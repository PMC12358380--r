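#' Hormone trajectory container
#'
#' Holds a sampled hormone time course: a strictly increasing time grid, a
#' `T x N` matrix of non-negative concentrations and a `T x N` matrix of the
#' stimuli that were applied at the sample times.
#'
#' @param times strictly increasing numeric vector of length `T`.
#' @param states `T x N` matrix of finite, non-negative concentrations.
#' @param inputs `T x N` matrix of applied stimuli (defaults to zero).
#' @param gland_names optional column names.
#' @return an object of class `"hormone_trajectory"`.
#' @export
hormone_trajectory <- function(times, states, inputs = NULL,
                               gland_names = NULL) {
  times <- as.numeric(times)
  states <- as.matrix(states)
  if (length(times) != nrow(states))
    stop("times and states must have matching lengths", call. = FALSE)
  if (any(!is.finite(times)) || any(diff(times) <= 0))
    stop("times must be finite and strictly increasing", call. = FALSE)
  if (any(!is.finite(states)))
    stop("states must be finite", call. = FALSE)
  if (any(states < 0))
    stop("states must be non-negative", call. = FALSE)
  if (is.null(inputs)) inputs <- matrix(0, nrow(states), ncol(states))
  inputs <- as.matrix(inputs)
  if (!all(dim(inputs) == dim(states)))
    stop("inputs must have the same shape as states", call. = FALSE)
  if (!is.null(gland_names)) {
    colnames(states) <- gland_names
    colnames(inputs) <- gland_names
  }
  structure(list(times = times, states = states, inputs = inputs),
            class = "hormone_trajectory")
}

#' @export
print.hormone_trajectory <- function(x, ...) {
  cat("Hormone trajectory:", nrow(x$states), "time points,",
      ncol(x$states), "glands, t in [",
      format(x$times[1]), ",", format(x$times[length(x$times)]), "]\n")
  cat("final state:", paste(signif(x$states[nrow(x$states), ], 5),
                            collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.hormone_trajectory <- function(x, ...) {
  N <- ncol(x$states)
  gl <- colnames(x$states)
  if (is.null(gl)) gl <- paste0("g", seq_len(N))
  df <- data.frame(time = x$times, x$states, check.names = FALSE)
  names(df) <- c("time", gl)
  if (any(x$inputs != 0)) {
    u <- as.data.frame(x$inputs)
    names(u) <- paste0("u_", gl)
    df <- cbind(df, u)
  }
  df
}

#' @export
plot.hormone_trajectory <- function(x, ...) {
  graphics::matplot(x$times, x$states, type = "l", lty = 1,
                    xlab = "time", ylab = "concentration", ...)
  gl <- colnames(x$states)
  if (!is.null(gl))
    graphics::legend("topright", legend = gl, lty = 1,
                     col = seq_len(ncol(x$states)), bty = "n")
  invisible(x)
}
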