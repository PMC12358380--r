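#' Read and write hormone trajectories as CSV
#'
#' Delimited text with header `time,<gland1>,...,<glandN>[,u_<gland1>,...]`.
#' Values are written with 15 significant digits so that a round trip is
#' lossless to at least 12 significant digits.
#'
#' @param traj a [hormone_trajectory()].
#' @param path file path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a [hormone_trajectory()].
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  df[] <- lapply(df, function(col) format(col, digits = 15, trim = TRUE,
                                          scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1L] != "time")
    stop("trajectory file must start with a 'time' column", call. = FALSE)
  ucols <- grep("^u_", names(df))
  gcols <- setdiff(seq_along(df)[-1L], ucols)
  states <- as.matrix(df[gcols])
  inputs <- if (length(ucols)) as.matrix(df[ucols]) else NULL
  hormone_trajectory(df$time, states, inputs,
                     gland_names = names(df)[gcols])
}

#' Save / load a forecaster bundle
#'
#' Serializes a forecaster (or [endo_forecaster()] fit; only the model is
#' stored) to a portable JSON archive: a manifest of the architecture
#' (dimensions, activation, slope, self-loop convention, seed) plus every
#' named parameter array at full precision. Loading validates the dimension
#' chain; saving a loaded bundle reproduces the file byte for byte.
#'
#' @param model a forecaster model or fit.
#' @param path file path (conventionally `.json`).
#' @return `save_forecaster` returns `path` invisibly; `load_forecaster`
#'   returns a `forecaster_model`.
#' @export
save_forecaster <- function(model, path) {
  if (inherits(model, "endo_forecaster")) model <- model$model
  stopifnot(inherits(model, "forecaster_model"))
  num <- function(x) sprintf("%.17g", as.numeric(x))
  pack <- function(x) {
    if (is.matrix(x)) list(dim = dim(x), data = num(x))
    else list(dim = length(x), data = num(x))
  }
  walk <- function(x) if (is.list(x)) lapply(x, walk) else pack(x)
  bundle <- list(
    manifest = list(
      format = "endoreg-forecaster", version = 1L,
      n_glands = model$n_glands, gland_names = model$gland_names,
      d = model$d, layers = model$layers, d_encoder = model$d_encoder,
      d_hidden = model$d_hidden, activation = model$activation,
      leaky_slope = model$leaky_slope, self_loops = model$self_loops,
      seed = model$seed,
      adjacency = list(dim = dim(model$adjacency$base),
                       data = num(model$adjacency$base))
    ),
    parameters = walk(model$par)
  )
  writeLines(jsonlite::toJSON(bundle, auto_unbox = TRUE, pretty = TRUE),
             path)
  invisible(path)
}

#' @rdname save_forecaster
#' @export
load_forecaster <- function(path) {
  bundle <- jsonlite::fromJSON(readLines(path), simplifyVector = TRUE,
                               simplifyDataFrame = FALSE,
                               simplifyMatrix = FALSE)
  man <- bundle$manifest
  if (!identical(man$format, "endoreg-forecaster"))
    stop("not a forecaster bundle: ", path, call. = FALSE)
  unpack <- function(x) {
    v <- as.numeric(x$data)
    if (length(x$dim) == 2L) matrix(v, x$dim[1L], x$dim[2L]) else v
  }
  walk <- function(x) {
    if (!is.null(x$data) && !is.null(x$dim)) unpack(x) else lapply(x, walk)
  }
  adj <- unpack(man$adjacency)
  model <- forecaster_init(adj, d = man$d, layers = man$layers,
                           d_encoder = man$d_encoder,
                           d_hidden = man$d_hidden,
                           activation = man$activation,
                           leaky_slope = man$leaky_slope,
                           self_loops = man$self_loops, seed = man$seed)
  model$gland_names <- man$gland_names
  par <- walk(bundle$parameters)
  # validate the dimension chain against a freshly initialized skeleton
  check <- function(ref, got, where) {
    if (is.list(ref)) {
      if (!is.list(got) || !setequal(names(ref), names(got)))
        stop("bundle parameter block mismatch at ", where, call. = FALSE)
      for (nm in names(ref)) check(ref[[nm]], got[[nm]],
                                   paste(where, nm, sep = "/"))
    } else {
      dref <- if (is.matrix(ref)) dim(ref) else length(ref)
      dgot <- if (is.matrix(got)) dim(got) else length(got)
      if (!identical(as.integer(dref), as.integer(dgot)))
        stop("bundle dimension mismatch at ", where, call. = FALSE)
    }
  }
  check(model$par, par, "par")
  model$par <- par
  model
}
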