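#' Per-temperature chill units relative to a reference temperature
#'
#' The chill unit CU(T) measures the efficiency of one hour at chilling
#' temperature T for releasing bud dormancy. It is estimated as the mean
#' rising-phase slope of all chilling-response curves at T (one curve per
#' chilling duration), divided by the mean slope at the reference
#' temperature, so CU(reference) = 1 exactly.
#'
#' @param experiment A [sprouting_experiment()].
#' @param reference_temperature Reference chilling temperature in deg C
#'   (default 0).
#' @return A `chill_unit_table`: data frame with columns `temperature`,
#'   `mean_slope` (percent/day), `chill_unit` (dimensionless, >= 0) and
#'   `no_emergence` (`TRUE` when no curve at that temperature ever left 0%).
#'   The reference temperature is stored as an attribute.
#' @details Slopes of curves with no emergence enter the mean as 0, so a
#'   temperature at which only long chilling treatments produce sprouting
#'   still gets a small positive chill unit. Chill units are ratios of
#'   slopes, hence invariant to any uniform rescaling of counts.
#' @export
chill_unit_table <- function(experiment, reference_temperature = 0) {
  curves <- response_curves(experiment)
  temps <- vapply(curves, `[[`, 0, "temperature")
  if (!any(temps == reference_temperature)) {
    stop(sprintf("reference temperature %g degC not present in experiment",
                 reference_temperature))
  }
  slopes <- lapply(curves, curve_slope)
  sl <- vapply(slopes, `[[`, 0, "slope")
  flat <- vapply(slopes, `[[`, TRUE, "no_emergence")
  out <- do.call(rbind, lapply(split(seq_along(sl), temps), function(idx) {
    data.frame(temperature = temps[idx[1]],
               mean_slope = mean(sl[idx]),
               no_emergence = all(flat[idx]))
  }))
  out <- out[order(out$temperature), , drop = FALSE]
  rownames(out) <- NULL
  ref_slope <- out$mean_slope[out$temperature == reference_temperature]
  if (ref_slope <= 0) {
    stop("reference temperature shows no emergence: cannot form chill units")
  }
  out$chill_unit <- out$mean_slope / ref_slope
  out$chill_unit[out$temperature == reference_temperature] <- 1
  out <- out[c("temperature", "mean_slope", "chill_unit", "no_emergence")]
  structure(out, class = c("chill_unit_table", "data.frame"),
            reference_temperature = reference_temperature)
}

#' Quadratic chill-unit model CU(T) = a T^2 + b T + c
#'
#' Constructs the concave quadratic relating chilling temperature (deg C) to
#' chill unit (CU, dimensionless relative to the reference temperature),
#' together with its derived constants: the optimum temperature
#' `t_opt = -b/(2a)`, the maximum chill unit `cu_max = c - b^2/(4a)`, and the
#' upper temperature limit `t_upper` (larger real root of the quadratic),
#' above which chilling makes no contribution.
#'
#' @param a,b,c Quadratic coefficients; `a` must be negative (an interior
#'   optimum must exist) and the maximum must be positive.
#' @param r_squared Optional goodness of fit carried from [fit_cu_model()].
#' @return An object of class `chill_unit_model`.
#' @examples
#' m <- chill_unit_model(-0.0154, 0.0916, 0.9926)
#' optimum_temperature(m)  # about 2.97 degC
#' cu_max(m)               # about 1.1288 CU
#' upper_limit(m)          # about 11.54 degC
#' @export
chill_unit_model <- function(a, b, c, r_squared = NA_real_) {
  check_number(a, "a"); check_number(b, "b"); check_number(c, "c")
  if (a >= 0) {
    stop("no interior optimum: quadratic coefficient 'a' must be negative")
  }
  t_opt <- -b / (2 * a)
  cu_peak <- c - b^2 / (4 * a)
  if (cu_peak <= 0) {
    stop("degenerate chill-unit model: maximum chill unit is not positive")
  }
  disc <- b^2 - 4 * a * c
  t_upper <- (-b - sqrt(disc)) / (2 * a)  # larger root since a < 0
  structure(list(a = a, b = b, c = c,
                 t_opt = t_opt, cu_max = cu_peak, t_upper = t_upper,
                 r_squared = r_squared,
                 valid_range = c(0, t_upper)),
            class = "chill_unit_model")
}

#' @export
print.chill_unit_model <- function(x, ...) {
  cat(sprintf("<chill_unit_model> CU(T) = %g T^2 + %g T + %g\n", x$a, x$b, x$c))
  cat(sprintf("  optimum %.2f degC, max %.4f CU, upper limit %.2f degC",
              x$t_opt, x$cu_max, x$t_upper))
  if (!is.na(x$r_squared)) cat(sprintf(", R^2 = %.4f", x$r_squared))
  cat("\n")
  invisible(x)
}

#' Fit the quadratic chill-unit model to a chill-unit table
#'
#' Ordinary least-squares fit of `chill_unit ~ temperature + temperature^2`
#' (unweighted). Rows flagged `no_emergence` are dropped by default: flat
#' curves carry no slope information and lie outside the model's effective
#' temperature range.
#'
#' @param table A [chill_unit_table()].
#' @param drop_no_emergence Drop flagged rows before fitting (default `TRUE`).
#' @return A [chill_unit_model()] with `r_squared` filled in.
#' @export
fit_cu_model <- function(table, drop_no_emergence = TRUE) {
  stopifnot(inherits(table, "chill_unit_table"))
  df <- as.data.frame(table)
  if (drop_no_emergence) df <- df[!df$no_emergence, , drop = FALSE]
  if (length(unique(df$temperature)) < 3) {
    stop("underdetermined: need >= 3 distinct temperatures to fit a quadratic")
  }
  fit <- stats::lm(chill_unit ~ temperature + I(temperature^2), data = df)
  cf <- stats::coef(fit)
  if (cf[[3]] >= 0) {
    stop("no interior optimum: fitted quadratic opens upward")
  }
  chill_unit_model(a = cf[[3]], b = cf[[2]], c = cf[[1]],
                   r_squared = summary(fit)$r.squared)
}

#' Evaluate the chill-unit model at given temperatures
#'
#' Returns `a T^2 + b T + c` clamped to 0 for temperatures outside
#' `[0, t_upper]` and wherever the polynomial is negative: there is no
#' anti-chilling term, temperatures above the upper limit contribute
#' nothing, and sub-zero temperatures are outside the model's domain
#' (they damage buds rather than chilling them efficiently) so they
#' contribute 0 with a warning.
#'
#' @param model A [chill_unit_model()].
#' @param temperature Numeric vector of temperatures (deg C).
#' @return Chill units (CU), same length as `temperature`.
#' @export
cu_value <- function(model, temperature) {
  stopifnot(inherits(model, "chill_unit_model"))
  if (any(!is.finite(temperature))) stop("temperature must be finite")
  if (any(temperature < 0)) {
    warning("temperature(s) below 0 degC are outside the model domain and contribute 0 CU")
  }
  y <- model$a * temperature^2 + model$b * temperature + model$c
  y[temperature < 0 | temperature > model$t_upper] <- 0
  pmax(y, 0)
}

#' Derived constants of the chill-unit model
#'
#' `optimum_temperature()` is the temperature of maximum chilling efficiency,
#' `-b/(2a)`; `cu_max()` the chill unit attained there, `c - b^2/(4a)`; and
#' `upper_limit()` the larger real root of the quadratic, the temperature at
#' and above which chilling is ineffective.
#'
#' @param model A [chill_unit_model()].
#' @return A single number (deg C, CU, and deg C respectively).
#' @export
optimum_temperature <- function(model) {
  stopifnot(inherits(model, "chill_unit_model"))
  model$t_opt
}

#' @rdname optimum_temperature
#' @export
cu_max <- function(model) {
  stopifnot(inherits(model, "chill_unit_model"))
  model$cu_max
}

#' @rdname optimum_temperature
#' @export
upper_limit <- function(model) {
  stopifnot(inherits(model, "chill_unit_model"))
  model$t_upper
}
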