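#' Load and validate a structured configuration file
#'
#' Reads a YAML configuration and validates it against one of the built-in
#' schemas, filling defaults for optional keys and rejecting unknown keys
#' with an error naming the offending path. The resulting object is the
#' corresponding package type.
#'
#' Schemas:
#' * `"network"`: `glands` (names), `coupling` (rows), `degradation`,
#'   optional `response` (string or matrix of strings), `K`, `n` -> a
#'   [gland_network()].
#' * `"schedule"`: `pulses`: list of `{target, dose, start, end}` -> an
#'   [intervention_schedule()] (`target` may be a gland name when `glands`
#'   is also given).
#' * `"dataset"`: fields of [synthetic_dataset_spec()].
#' * `"train"`: fields of [training_config()] plus optional architecture
#'   keys `d`, `layers`, `d_encoder`, `d_hidden`, `activation`,
#'   `leaky_slope`, `self_loops` -> list with `$config` and `$arch`.
#' * `"control"`: fields of [control_config()] -> a [control_config()].
#'
#' @param path YAML file path.
#' @param schema one of `"network"`, `"schedule"`, `"dataset"`, `"train"`,
#'   `"control"`.
#' @return the validated object (see above).
#' @export
load_config <- function(path,
                        schema = c("network", "schedule", "dataset",
                                   "train", "control")) {
  schema <- match.arg(schema)
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)
  validate_config(raw, schema)
}

#' @rdname load_config
#' @param object a value previously produced by the same schema's loader
#'   (or the raw list form).
#' @export
dump_config <- function(object, path) {
  yaml::write_yaml(config_to_list(object), path)
  invisible(path)
}

config_to_list <- function(object) {
  if (inherits(object, "gland_network")) {
    types <- matrix(names(RESPONSE_CODES)[object$resp_type],
                    nrow(object$coupling))
    list(glands = object$gland_names,
         coupling = lapply(seq_len(nrow(object$coupling)), function(i)
           as.numeric(object$coupling[i, ])),
         degradation = as.numeric(object$degradation),
         response = lapply(seq_len(nrow(types)), function(i)
           as.character(types[i, ])),
         K = object$resp_K[1, 1], n = object$resp_n[1, 1])
  } else if (inherits(object, "intervention_schedule")) {
    list(pulses = lapply(seq_along(object$target), function(k)
      list(target = object$target[k], dose = object$dose[k],
           start = object$start[k], end = object$end[k])))
  } else if (inherits(object, "synthetic_dataset_spec")) {
    list(n_trajectories = object$n_trajectories, horizon = object$horizon,
         step = object$step,
         init_ranges = lapply(seq_len(nrow(object$init_ranges)), function(i)
           as.numeric(object$init_ranges[i, ])),
         noise_sd = object$noise_sd, seed = object$seed)
  } else if (inherits(object, "control_config")) {
    list(targets = as.numeric(object$targets),
         weights = as.numeric(object$weights),
         risk_weight = object$risk_weight,
         interaction_risk = lapply(seq_len(nrow(object$interaction_risk)),
                                   function(i)
                                     as.numeric(object$interaction_risk[i, ])),
         intervention_lr = object$intervention_lr, decay = object$decay,
         risk_threshold = object$risk_threshold, penalty = object$penalty,
         max_iters = object$max_iters,
         convergence_tol = object$convergence_tol, u_max = object$u_max,
         control_dt = object$control_dt)
  } else if (is.list(object) && !is.null(object$config) &&
             inherits(object$config, "training_config")) {
    c(unclass(object$config), object$arch)
  } else if (is.list(object)) object
  else stop("cannot serialize object of class ", class(object)[1L],
            call. = FALSE)
}

check_keys <- function(raw, required, optional, schema) {
  unknown <- setdiff(names(raw), c(required, optional))
  if (length(unknown))
    stop(schema, " config: unknown key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop(schema, " config: missing required key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

validate_config <- function(raw, schema) {
  switch(schema,
    network = {
      check_keys(raw, c("glands", "coupling", "degradation"),
                 c("response", "K", "n"), "network")
      coupling <- do.call(rbind, lapply(raw$coupling, as.numeric))
      response <- raw$response
      if (is.list(response)) {
        response <- do.call(rbind, lapply(response, as.character))
      }
      if (is.null(response)) response <- "identity"
      gland_network(as.character(raw$glands), coupling,
                    as.numeric(raw$degradation), response = response,
                    K = raw$K %||% 1, n = raw$n %||% 2)
    },
    schedule = {
      check_keys(raw, "pulses", "glands", "schedule")
      pulses <- raw$pulses
      resolve_target <- function(tg) {
        if (is.character(tg)) {
          i <- match(tg, raw$glands)
          if (is.na(i)) stop("schedule config: unknown gland '", tg, "'",
                             call. = FALSE)
          i
        } else as.integer(tg)
      }
      for (k in seq_along(pulses))
        check_keys(pulses[[k]], c("target", "dose", "start", "end"),
                   character(), sprintf("schedule pulse %d", k))
      intervention_schedule(
        target = vapply(pulses, function(p) resolve_target(p$target), 1L),
        dose = vapply(pulses, function(p) as.numeric(p$dose), 1),
        start = vapply(pulses, function(p) as.numeric(p$start), 1),
        end = vapply(pulses, function(p) as.numeric(p$end), 1))
    },
    dataset = {
      check_keys(raw, "n_trajectories",
                 c("horizon", "step", "init_ranges", "noise_sd", "seed"),
                 "dataset")
      ir <- raw$init_ranges
      if (is.list(ir)) ir <- do.call(rbind, lapply(ir, as.numeric))
      args <- list(n_trajectories = raw$n_trajectories)
      for (nm in c("horizon", "step", "noise_sd", "seed"))
        if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
      if (!is.null(ir)) args$init_ranges <- ir
      do.call(synthetic_dataset_spec, args)
    },
    train = {
      cfg_keys <- setdiff(names(formals(training_config)), "")
      arch_keys <- c("d", "layers", "d_encoder", "d_hidden", "activation",
                     "leaky_slope", "self_loops")
      check_keys(raw, character(), c(cfg_keys, arch_keys), "train")
      cfg <- do.call(training_config, raw[intersect(names(raw), cfg_keys)])
      list(config = cfg, arch = raw[intersect(names(raw), arch_keys)])
    },
    control = {
      keys <- names(formals(control_config))
      check_keys(raw, "targets", setdiff(keys, "targets"), "control")
      if (is.list(raw$interaction_risk))
        raw$interaction_risk <- do.call(rbind,
                                        lapply(raw$interaction_risk,
                                               as.numeric))
      do.call(control_config, raw)
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
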