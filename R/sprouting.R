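#' Replicated sprouting time-course experiment
#'
#' A `sprouting_experiment` holds cumulative bud-sprouting counts recorded
#' daily under warm conditions, after trays of buds were chilled at a given
#' temperature for a given number of days. Each record is one tray
#' (replicate): `n_buds` buds chilled at `temperature` (deg C) for
#' `chilling_days` days, then moved to warm conditions, with
#' `sprouted` the cumulative number of sprouted buds on warming `day`
#' (day 1 = first day under warm conditions).
#'
#' @param records A data frame in long format with columns
#'   `temperature`, `chilling_days`, `replicate`, `n_buds`, `day`,
#'   `sprouted`. One row per (tray, warming day).
#' @return An object of class `sprouting_experiment` (a validated long
#'   data frame).
#' @details Validation enforces: `n_buds > 0`; `chilling_days >= 0`;
#'   `0 <= sprouted <= n_buds`; and cumulative counts non-decreasing in
#'   `day` within each tray. Violations are errors that name the offending
#'   row -- counts are never silently repaired.
#' @examples
#' rec <- data.frame(temperature = 0, chilling_days = 15, replicate = 1,
#'                   n_buds = 20, day = 1:3, sprouted = c(0, 1, 3))
#' exp <- sprouting_experiment(rec)
#' @export
sprouting_experiment <- function(records) {
  required <- c("temperature", "chilling_days", "replicate", "n_buds",
                "day", "sprouted")
  if (!is.data.frame(records)) stop("'records' must be a data frame")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("sprouting schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  records <- as.data.frame(records)[required]
  for (col in c("temperature", "chilling_days", "n_buds", "day", "sprouted")) {
    if (!is.numeric(records[[col]])) {
      stop("sprouting schema error: column '", col, "' must be numeric")
    }
  }
  if (any(records$n_buds <= 0)) {
    stop("validation error: n_buds must be positive (row ",
         which(records$n_buds <= 0)[1], ")")
  }
  if (any(records$chilling_days < 0)) {
    stop("validation error: chilling_days must be >= 0 (row ",
         which(records$chilling_days < 0)[1], ")")
  }
  bad <- which(records$sprouted < 0 | records$sprouted > records$n_buds)
  if (length(bad) > 0) {
    stop(sprintf(
      "validation error: sprouted count %g outside [0, n_buds = %g] (row %d)",
      records$sprouted[bad[1]], records$n_buds[bad[1]], bad[1]))
  }
  # order by tray then day, then check cumulative monotonicity per tray
  key <- interaction(records$temperature, records$chilling_days,
                     records$replicate, drop = TRUE)
  ord <- order(key, records$day)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  key <- key[ord]
  for (tray in split(seq_len(nrow(records)), key)) {
    s <- records$sprouted[tray]
    drops <- which(diff(s) < 0)
    if (length(drops) > 0) {
      stop(sprintf(
        "validation error: cumulative sprouted count decreases at row %d (%g -> %g)",
        tray[drops[1] + 1], s[drops[1]], s[drops[1] + 1]))
    }
    nb <- unique(records$n_buds[tray])
    if (length(nb) != 1) {
      stop("validation error: n_buds varies within one tray (rows ",
           tray[1], "...)")
    }
  }
  structure(records, class = c("sprouting_experiment", "data.frame"))
}

#' @export
print.sprouting_experiment <- function(x, ...) {
  tr <- treatments(x)
  cat(sprintf(
    "<sprouting_experiment> %d treatments (%d temperatures x %d durations), %d rows\n",
    nrow(tr), length(unique(tr$temperature)),
    length(unique(tr$chilling_days)), nrow(x)))
  invisible(x)
}

#' Distinct chilling treatments of an experiment
#'
#' @param experiment A [sprouting_experiment()].
#' @return Data frame with one row per distinct
#'   (`temperature`, `chilling_days`) pair and the replicate count.
#' @export
treatments <- function(experiment) {
  stopifnot(inherits(experiment, "sprouting_experiment"))
  df <- as.data.frame(experiment)
  ag <- stats::aggregate(replicate ~ temperature + chilling_days, data = df,
                         FUN = function(r) length(unique(r)))
  names(ag)[3] <- "n_replicates"
  ag[order(ag$temperature, ag$chilling_days), , drop = FALSE]
}

#' Replicate-mean chilling-response curves
#'
#' Collapses an experiment to one cumulative sprouting-percentage curve per
#' (temperature, chilling duration) treatment, averaging
#' `100 * sprouted / n_buds` over replicates at each warming day.
#'
#' @param experiment A [sprouting_experiment()].
#' @return A list of `chill_response_curve` objects, each a list with
#'   elements `temperature`, `chilling_days`, `day` and `sprouting_pct`
#'   (values in \[0, 100\], non-decreasing over warming days).
#' @export
response_curves <- function(experiment) {
  stopifnot(inherits(experiment, "sprouting_experiment"))
  df <- as.data.frame(experiment)
  df$pct <- 100 * df$sprouted / df$n_buds
  key <- interaction(df$temperature, df$chilling_days, drop = TRUE)
  curves <- lapply(split(df, key), function(d) {
    m <- stats::aggregate(pct ~ day, data = d, FUN = mean)
    m <- m[order(m$day), , drop = FALSE]
    structure(list(temperature = d$temperature[1],
                   chilling_days = d$chilling_days[1],
                   day = m$day, sprouting_pct = m$pct),
              class = "chill_response_curve")
  })
  ord <- order(vapply(curves, `[[`, 0, "temperature"),
               vapply(curves, `[[`, 0, "chilling_days"))
  curves <- curves[ord]
  names(curves) <- vapply(curves, function(cv)
    sprintf("T%g_d%g", cv$temperature, cv$chilling_days), "")
  curves
}

#' @export
print.chill_response_curve <- function(x, ...) {
  cat(sprintf("<chill_response_curve> %g degC x %g d, final %.1f%% (%d days)\n",
              x$temperature, x$chilling_days,
              max(x$sprouting_pct), length(x$day)))
  invisible(x)
}

#' Value of a cumulative response curve at a warming day
#'
#' Cumulative curves are step functions between recorded days: the value at
#' `day` is the value at the latest recorded day `<= day` (0 before the
#' first record).
#'
#' @param curve A `chill_response_curve`.
#' @param day Warming day (scalar).
#' @return Sprouting percentage at `day`.
#' @keywords internal
curve_value_at <- function(curve, day) {
  idx <- which(curve$day <= day)
  if (length(idx) == 0) return(0)
  curve$sprouting_pct[max(idx)]
}

#' Rising-phase slope of a chilling-response curve
#'
#' The slope summarises how fast buds emerge once warming starts. It is the
#' ordinary least-squares slope of sprouting percentage against warming day
#' restricted to the rising window, from the first day with a positive value
#' to the first day reaching the curve's maximum. When that window contains a
#' single day, the last pre-emergence day is included (or an implied 0% at
#' day 0 when emergence happens on day 1) so the slope is still defined.
#'
#' @param curve A `chill_response_curve`.
#' @return A list with `slope` (percent per day), `no_emergence` (`TRUE` when
#'   the curve never leaves 0, in which case `slope` is 0), and `window`
#'   (first/last day used).
#' @export
curve_slope <- function(curve) {
  stopifnot(inherits(curve, "chill_response_curve"))
  p <- curve$sprouting_pct
  d <- curve$day
  if (max(p) <= 0) {
    return(list(slope = 0, no_emergence = TRUE, window = c(NA_real_, NA_real_)))
  }
  i1 <- which(p > 0)[1]
  i2 <- which(p >= max(p))[1]
  if (i1 == i2) {
    if (i1 > 1) {
      i1 <- i1 - 1L
    } else {
      # emergence on the first recorded day: anchor at (day - 1, 0%)
      d <- c(d[1] - 1, d)
      p <- c(0, p)
      i2 <- i2 + 1L
    }
  }
  dd <- d[i1:i2]
  pp <- p[i1:i2]
  slope <- sum((dd - mean(dd)) * (pp - mean(pp))) / sum((dd - mean(dd))^2)
  list(slope = slope, no_emergence = FALSE, window = c(dd[1], dd[length(dd)]))
}
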