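#' Time schedule for an externally controlled parameter
#'
#' Describes how a single model parameter (the toy tilt \code{beta}, or the LIF
#' concentration \code{L}) varies with simulation time. Three modes:
#' \code{"constant"}, \code{"linear"} (ramp from \code{from} to \code{to} over
#' \code{duration}, then held at \code{to}), and \code{"step"} (jump from
#' \code{from} to \code{to} at \code{duration}).
#'
#' The shipped experiment recipes use \code{beta = t - 0.5} (a linear ramp from
#' -0.5 to 0.5 over one time unit) and \code{L = 150 (1 - t / T_ramp)} with a
#' configurable ramp duration.
#'
#' @param parameter name of the scheduled parameter, e.g. \code{"beta"}, \code{"L"}.
#' @param mode one of \code{"constant"}, \code{"linear"}, \code{"step"}.
#' @param from start value (the constant value in mode \code{"constant"}).
#' @param to end value; ignored for constant schedules.
#' @param duration ramp duration (or step time) in simulation time units; must
#'   be positive for non-constant modes.
#' @return Object of class \code{param_schedule}.
#' @examples
#' sch <- param_schedule("L", "linear", from = 150, to = 0, duration = 2000)
#' schedule_value(sch, c(0, 1000, 2000, 3000))
#' @export
param_schedule <- function(parameter, mode = c("constant", "linear", "step"),
                           from, to = from, duration = NA_real_) {
  mode <- match.arg(mode)
  stopifnot(is.character(parameter), length(parameter) == 1L)
  if (!is.finite(from) || !is.finite(to)) stop("schedule endpoints must be finite")
  if (mode != "constant") {
    if (!is.finite(duration) || duration <= 0) {
      stop("'duration' must be positive for ", mode, " schedules")
    }
  }
  structure(
    list(parameter = parameter, mode = mode, from = from, to = to,
         duration = duration),
    class = "param_schedule"
  )
}

#' Constant schedule shorthand
#' @param parameter parameter name.
#' @param value the constant value.
#' @export
constant_schedule <- function(parameter, value) {
  param_schedule(parameter, "constant", from = value)
}

#' Evaluate a schedule at given times
#'
#' @param schedule a [param_schedule()].
#' @param t numeric vector of times.
#' @return Numeric vector of parameter values, finite everywhere.
#' @export
schedule_value <- function(schedule, t) {
  stopifnot(inherits(schedule, "param_schedule"))
  switch(schedule$mode,
    constant = rep(schedule$from, length(t)),
    linear = {
      frac <- pmin(pmax(t / schedule$duration, 0), 1)
      schedule$from + (schedule$to - schedule$from) * frac
    },
    step = ifelse(t < schedule$duration, schedule$from, schedule$to)
  )
}

# Integer mode code shared with the C++ kernels.
schedule_mode_code <- function(schedule) {
  match(schedule$mode, c("constant", "linear", "step")) - 1L
}

# Resolve a possibly-NULL schedule against a model: returns a list with the
# C++-ready fields and validates the parameter name.
resolve_schedule <- function(model, schedule) {
  if (is.null(schedule)) {
    return(list(mode = 0L, from = 0, to = 0, duration = 0, parameter = NA_character_))
  }
  stopifnot(inherits(schedule, "param_schedule"))
  if (!schedule$parameter %in% names(model$params)) {
    stop(sprintf(
      "schedule parameter '%s' is not a parameter of the %s model",
      schedule$parameter, model$id
    ))
  }
  list(
    mode = schedule_mode_code(schedule),
    from = schedule$from, to = schedule$to,
    duration = if (is.na(schedule$duration)) 0 else schedule$duration,
    parameter = schedule$parameter
  )
}
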