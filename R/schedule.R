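#' Intervention schedules
#'
#' A schedule is a set of rectangular dose pulses: pulse `k` applies a
#' constant dose `dose[k] >= 0` to gland `target[k]` over the closed time
#' window `[start[k], end[k]]`. Outside the window the contribution is zero;
#' overlapping pulses on the same gland sum.
#'
#' @param target integer gland indices (one per pulse).
#' @param dose non-negative doses, in concentration-rate units.
#' @param start,end window endpoints, `start <= end` componentwise.
#' @return an object of class `"intervention_schedule"`.
#' @examples
#' sched <- intervention_schedule(target = 1, dose = 3, start = 1, end = 2)
#' stimulus_at(sched, 1.5, n = 2) # c(3, 0)
#' stimulus_at(sched, 0.5, n = 2) # c(0, 0)
#' @export
intervention_schedule <- function(target = integer(), dose = numeric(),
                                  start = numeric(), end = numeric()) {
  k <- max(length(target), length(dose), length(start), length(end))
  if (k > 0) {
    target <- rep_len(as.integer(target), k)
    dose <- rep_len(as.numeric(dose), k)
    start <- rep_len(as.numeric(start), k)
    end <- rep_len(as.numeric(end), k)
    if (any(!is.finite(dose)) || any(dose < 0))
      stop("doses must be finite and non-negative", call. = FALSE)
    if (any(!is.finite(start)) || any(!is.finite(end)) || any(start > end))
      stop("pulse windows must satisfy start <= end", call. = FALSE)
    if (any(is.na(target)) || any(target < 1L))
      stop("pulse targets must be positive gland indices", call. = FALSE)
  }
  structure(
    list(target = as.integer(target), dose = dose, start = start, end = end),
    class = "intervention_schedule"
  )
}

#' @export
print.intervention_schedule <- function(x, ...) {
  k <- length(x$target)
  cat("Intervention schedule with", k, "pulse(s)\n")
  if (k > 0)
    print(data.frame(target = x$target, dose = x$dose,
                     start = x$start, end = x$end))
  invisible(x)
}

#' Evaluate a schedule at a time point
#'
#' Returns the stimulus vector `u(t)`: component `i` is the sum of the doses
#' of all pulses targeting gland `i` whose closed window contains `t`.
#'
#' @param schedule an [intervention_schedule()] (or `NULL` for no stimulus).
#' @param t a finite time point.
#' @param n number of glands (output length).
#' @return numeric stimulus vector of length `n`.
#' @export
stimulus_at <- function(schedule, t, n) {
  u <- numeric(n)
  if (is.null(schedule) || length(schedule$target) == 0L) return(u)
  if (!is.finite(t)) stop("t must be finite", call. = FALSE)
  if (any(schedule$target > n))
    stop("schedule targets a gland index beyond the network size ", n,
         call. = FALSE)
  active <- schedule$start <= t & t <= schedule$end
  if (any(active)) {
    for (k in which(active))
      u[schedule$target[k]] <- u[schedule$target[k]] + schedule$dose[k]
  }
  u
}
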