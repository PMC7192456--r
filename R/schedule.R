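#' Temperature schedules and chilling accumulation
#'
#' A `temperature_schedule` is an ordered list of segments, each holding a
#' constant temperature for a positive number of hours. Chilling accumulation
#' (Ca, in CU hours) integrates the chill-unit model over such a schedule:
#' each hour at temperature T contributes CU(T).
#'
#' @param hours Numeric vector of positive segment durations (hours).
#' @param temperature Numeric vector of segment temperatures (deg C), same
#'   length as `hours`.
#' @return An object of class `temperature_schedule` (a data frame with
#'   columns `hours` and `temperature`). The empty schedule is allowed and
#'   accumulates 0 Ca.
#' @export
temperature_schedule <- function(hours = numeric(0), temperature = numeric(0)) {
  if (length(hours) != length(temperature)) {
    stop("'hours' and 'temperature' must have the same length")
  }
  if (any(!is.finite(hours)) || any(hours <= 0)) {
    stop("segment durations must be positive and finite")
  }
  if (any(!is.finite(temperature))) stop("temperatures must be finite")
  structure(data.frame(hours = as.numeric(hours),
                       temperature = as.numeric(temperature)),
            class = c("temperature_schedule", "data.frame"))
}

#' @export
print.temperature_schedule <- function(x, ...) {
  cat(sprintf("<temperature_schedule> %d segment(s), %g h total\n",
              nrow(x), sum(x$hours)))
  invisible(x)
}

#' Constant-temperature schedule
#'
#' Convenience wrapper for the constant-temperature chilling treatments:
#' `days` days at `temperature`, counted as 24 h per day.
#'
#' @param temperature Temperature in deg C.
#' @param days Number of days (> 0).
#' @return A [temperature_schedule()] with a single segment.
#' @export
constant_schedule <- function(temperature, days) {
  check_number(temperature, "temperature")
  check_number(days, "days")
  if (days <= 0) stop("'days' must be positive")
  temperature_schedule(hours = 24 * days, temperature = temperature)
}

#' Ramped temperature schedule
#'
#' Builds the verification-style schedule in which temperature rises from
#' `start` to `end` in daily increments of `step` deg C (one 24-hour segment
#' per ramp temperature, endpoints included) and is then held at `end` for
#' `hold_days` days. A ramp from 0 to 10 deg C at 1 deg C/day therefore has
#' 11 ramp days before the hold.
#'
#' @param start,end Ramp endpoint temperatures in deg C (`end >= start`).
#' @param step Daily increment in deg C/day (> 0), default 1.
#' @param hold_days Days held at `end` after the ramp (>= 0).
#' @return A [temperature_schedule()].
#' @export
ramp_schedule <- function(start, end, step = 1, hold_days = 0) {
  check_number(start, "start"); check_number(end, "end")
  check_number(step, "step"); check_number(hold_days, "hold_days")
  if (step <= 0) stop("'step' must be positive")
  if (end < start) stop("'end' must be >= 'start'")
  if (hold_days < 0) stop("'hold_days' must be >= 0")
  temps <- seq(start, end, by = step)
  hours <- rep(24, length(temps))
  if (hold_days > 0) {
    temps <- c(temps, end)
    hours <- c(hours, 24 * hold_days)
  }
  temperature_schedule(hours = hours, temperature = temps)
}

#' Chilling accumulation over a temperature schedule
#'
#' Ca = sum over segments of CU(T) x hours, in CU hours. Additive over
#' concatenated schedules and invariant to subdividing a segment. Segments
#' outside the model's effective range (below 0 deg C or above the upper
#' limit) contribute 0.
#'
#' @param model A [chill_unit_model()].
#' @param schedule A [temperature_schedule()].
#' @return Chilling accumulation in Ca (CU hours).
#' @export
chilling_accumulation <- function(model, schedule) {
  stopifnot(inherits(model, "chill_unit_model"),
            inherits(schedule, "temperature_schedule"))
  if (nrow(schedule) == 0) return(0)
  sum(cu_value(model, schedule$temperature) * schedule$hours)
}
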