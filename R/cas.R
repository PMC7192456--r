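#' Stage-wise accumulation-to-sprouting (CAS) model
#'
#' A `cas_stage_model` maps chilling accumulation Ca (CU hours) to the
#' sprouting percentage reached by a fixed warming day (the "stage", e.g.
#' day 37, 40, 44 or 50). The default functional form is quadratic,
#' p(Ca) = alpha Ca^2 + beta Ca + gamma, whose vertex (for alpha < 0) is the
#' optimum chilling requirement for that stage.
#'
#' @param stage_day Warming day the model describes.
#' @param alpha,beta,gamma Quadratic coefficients.
#' @param r_squared Optional goodness of fit.
#' @return An object of class `cas_stage_model`. `has_optimum` is `TRUE`
#'   when `alpha < 0` (an interior optimum exists); models with
#'   `alpha >= 0` are stored with a "no optimum" flag rather than rejected.
#' @export
cas_stage_model <- function(stage_day, alpha, beta, gamma,
                            r_squared = NA_real_) {
  check_number(stage_day, "stage_day")
  check_number(alpha, "alpha"); check_number(beta, "beta")
  check_number(gamma, "gamma")
  structure(list(stage_day = stage_day, alpha = alpha, beta = beta,
                 gamma = gamma, has_optimum = alpha < 0,
                 r_squared = r_squared),
            class = "cas_stage_model")
}

#' @export
print.cas_stage_model <- function(x, ...) {
  cat(sprintf("<cas_stage_model> day %g: p(Ca) = %g Ca^2 + %g Ca + %g",
              x$stage_day, x$alpha, x$beta, x$gamma))
  if (!is.na(x$r_squared)) cat(sprintf(" (R^2 = %.4f)", x$r_squared))
  cat("\n")
  if (x$has_optimum) {
    cat(sprintf("  optimum Ca = %.0f\n", optimum_ca(x)))
  } else {
    cat("  no interior optimum (alpha >= 0)\n")
  }
  invisible(x)
}

#' Accumulation/sprouting observations at a warming-day stage
#'
#' For each constant-temperature chilling treatment in the experiment,
#' computes its chilling accumulation Ca = CU(T) x 24 h x chilling days
#' under `model`, and reads the replicate-mean sprouting percentage reached
#' by `stage_day`. Treatments whose temperature has zero chill unit (outside
#' the model's effective range) deliver no chilling and are excluded.
#'
#' @param experiment A [sprouting_experiment()].
#' @param model A [chill_unit_model()].
#' @param stage_day Warming day at which to read sprouting (must lie within
#'   the recorded warming-day range).
#' @return Data frame with columns `temperature`, `chilling_days`, `ca`
#'   and `sprouting_pct` (one row per treatment with Ca > 0).
#' @export
stage_observations <- function(experiment, model, stage_day) {
  stopifnot(inherits(experiment, "sprouting_experiment"),
            inherits(model, "chill_unit_model"))
  check_number(stage_day, "stage_day")
  dmax <- max(experiment$day)
  if (stage_day < min(experiment$day) || stage_day > dmax) {
    stop(sprintf("stage_day %g outside recorded warming-day range [%g, %g]",
                 stage_day, min(experiment$day), dmax))
  }
  curves <- response_curves(experiment)
  rows <- lapply(curves, function(cv) {
    cu <- suppressWarnings(cu_value(model, cv$temperature))
    ca <- cu * 24 * cv$chilling_days
    if (ca <= 0) return(NULL)
    data.frame(temperature = cv$temperature, chilling_days = cv$chilling_days,
               ca = ca, sprouting_pct = curve_value_at(cv, stage_day))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(temperature = numeric(0), chilling_days = numeric(0),
                      ca = numeric(0), sprouting_pct = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Fit a stage-wise CAS model
#'
#' Ordinary least-squares fit of sprouting percentage on chilling
#' accumulation, quadratic by default.
#'
#' @param points Data frame with columns `ca` and `sprouting_pct`
#'   (as from [stage_observations()]).
#' @param stage_day Warming day the points were read at.
#' @param form Functional form; only `"quadratic"` is implemented.
#' @return A [cas_stage_model()].
#' @export
fit_cas <- function(points, stage_day, form = "quadratic") {
  form <- match.arg(form, "quadratic")
  if (!all(c("ca", "sprouting_pct") %in% names(points))) {
    stop("'points' must have columns 'ca' and 'sprouting_pct'")
  }
  if (length(unique(points$ca)) < 3) {
    stop("underdetermined: need >= 3 distinct Ca values for a quadratic fit")
  }
  fit <- stats::lm(sprouting_pct ~ ca + I(ca^2), data = points)
  cf <- stats::coef(fit)
  cas_stage_model(stage_day = stage_day, alpha = cf[[3]], beta = cf[[2]],
                  gamma = cf[[1]], r_squared = summary(fit)$r.squared)
}

#' Predicted sprouting percentage at a chilling accumulation
#'
#' Evaluates the stage polynomial and clamps to \[0, 100\].
#'
#' @param cas A [cas_stage_model()].
#' @param ca Chilling accumulation(s), Ca >= 0.
#' @return Sprouting percentage(s) in \[0, 100\].
#' @export
predict_sprouting <- function(cas, ca) {
  stopifnot(inherits(cas, "cas_stage_model"))
  if (any(ca < 0)) stop("'ca' must be >= 0")
  clamp(cas$alpha * ca^2 + cas$beta * ca + cas$gamma, 0, 100)
}

#' Optimum chilling requirement of a stage model
#'
#' Vertex of the quadratic, -beta/(2 alpha); only defined for concave models.
#'
#' @param cas A [cas_stage_model()].
#' @return Optimum Ca.
#' @export
optimum_ca <- function(cas) {
  stopifnot(inherits(cas, "cas_stage_model"))
  if (!cas$has_optimum) {
    stop("no optimum: stage model is not concave (alpha >= 0)")
  }
  -cas$beta / (2 * cas$alpha)
}

#' Smallest chilling accumulation achieving a target sprouting percentage
#'
#' Returns the smallest Ca >= 0 with `predict_sprouting(cas, Ca) >= target`:
#' for a concave quadratic this is the lower crossing, the agronomically
#' meaningful "smallest sufficient chilling".
#'
#' @param cas A [cas_stage_model()].
#' @param target_pct Target sprouting percentage in (0, 100\].
#' @return Required Ca.
#' @export
required_ca <- function(cas, target_pct) {
  stopifnot(inherits(cas, "cas_stage_model"))
  check_number(target_pct, "target_pct")
  if (target_pct > 100) {
    stop("unachievable target: sprouting percentage cannot exceed 100")
  }
  model_max <- if (cas$has_optimum) {
    min(cas$gamma - cas$beta^2 / (4 * cas$alpha), 100)
  } else 100
  if (predict_sprouting(cas, 0) >= target_pct) return(0)
  tol <- 1e-9 * max(1, abs(target_pct))
  # real roots of alpha x^2 + beta x + (gamma - target) = 0
  roots <- if (abs(cas$alpha) > 0) {
    r <- polyroot(c(cas$gamma - target_pct, cas$beta, cas$alpha))
    Re(r[abs(Im(r)) < 1e-8 * (1 + abs(Re(r)))])
  } else if (cas$beta != 0) {
    (target_pct - cas$gamma) / cas$beta
  } else numeric(0)
  if (cas$has_optimum) roots <- c(roots, optimum_ca(cas))  # tangency case
  roots <- sort(roots[roots >= -tol])
  roots <- pmax(roots, 0)
  ok <- roots[predict_sprouting(cas, roots) >= target_pct - 1e-6]
  if (length(ok) == 0) {
    stop(sprintf(
      "unachievable target %.4g%%: model maximum is %.4g%%",
      target_pct, model_max))
  }
  ok[1]
}

#' Verification statistics for predicted vs observed sprouting
#'
#' Compares model predictions with observations: squared Pearson correlation
#' (R^2), ordinary least-squares slope and intercept of the
#' observed-on-predicted regression (so a perfect model gives the line
#' Y = X), and the mean signed bias (observed minus predicted).
#'
#' @param predicted,observed Equal-length numeric vectors (percent), n >= 3.
#' @return A list of class `cas_verification` with elements `n`,
#'   `r_squared`, `slope`, `intercept` and `bias`.
#' @export
verify_predictions <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop("length mismatch between predicted and observed")
  }
  n <- length(predicted)
  if (n < 3) stop("need at least 3 prediction/observation pairs")
  fit <- stats::lm(observed ~ predicted)
  structure(list(n = n,
                 r_squared = stats::cor(observed, predicted)^2,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 bias = mean(observed - predicted)),
            class = "cas_verification")
}

#' @export
print.cas_verification <- function(x, ...) {
  cat(sprintf(
    "<cas_verification> n = %d, R^2 = %.4f, observed = %.3f x predicted %+.3f, bias %+.3f\n",
    x$n, x$r_squared, x$slope, x$intercept, x$bias))
  invisible(x)
}
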