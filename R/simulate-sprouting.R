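#' Configuration for the sprouting-experiment simulator
#'
#' Defines the generating process for synthetic chilling/sprouting
#' experiments with known ground truth. For a tray chilled at temperature T
#' for `d` days, the chilling accumulation is Ca = CU_true(T) x 24 x d.
#' Each bud sprouts independently with probability `plateau(Ca)/100`; a
#' sprouting bud emerges on a warming day drawn from a logistic distribution
#' with location `delay(Ca)` and scale `1/rate`, rounded up to a whole day.
#'
#' The plateau rises with accumulation and declines gently beyond the
#' supra-optimal point: `plateau(Ca) = plateau_max (1 - exp(-Ca/plateau_scale))`
#' for `Ca <= supra_optimal_ca`, minus `supra_decline (Ca - supra_optimal_ca)`
#' beyond it, clamped to \[0, 100\]. The emergence delay decreases with
#' accumulation: `delay(Ca) = delay_min + delay_range exp(-Ca/delay_scale)`.
#' Emergence steepness increases with accumulation -- well-chilled trays
#' sprout quickly and uniformly, poorly chilled trays slowly and raggedly --
#' as `rate(Ca) = rate_min + rate_per_ca x Ca` (per day), so the rising-phase
#' slope of a curve carries the chilling signal, the feature the chill-unit
#' estimator relies on.
#'
#' @param true_cu The generating [chill_unit_model()]. Defaults to the
#'   fitted field model for *Polygonatum kingianum* rhizome buds.
#' @param temperatures Chilling temperatures (deg C). The default spans the
#'   full treatment design, including a sub-zero temperature and two above
#'   the upper limit, which deliver no chilling and produce flat curves.
#' @param durations Chilling durations (days).
#' @param n_buds Buds per tray.
#' @param replicates Trays per treatment.
#' @param n_warm_days Number of warming days recorded.
#' @param plateau_max,plateau_scale,supra_optimal_ca,supra_decline Plateau
#'   parameters (percent, Ca, Ca, percent per Ca).
#' @param delay_min,delay_range,delay_scale Delay parameters (days, days, Ca).
#' @param rate_min Baseline logistic steepness of within-tray emergence,
#'   per day (> 0).
#' @param rate_per_ca Increase in steepness per unit Ca (>= 0).
#' @param seed Integer seed; identical seeds reproduce identical experiments.
#' @return An object of class `sprouting_sim_config`.
#' @export
sprouting_sim_config <- function(
    true_cu = chill_unit_model(-0.0154, 0.0916, 0.9926),
    temperatures = c(-2, 0, 2, 4, 6, 8, 10, 12, 14),
    durations = c(5, 11, 15, 18, 22, 27, 32, 36, 52, 61, 71, 81),
    n_buds = 20, replicates = 3, n_warm_days = 70,
    plateau_max = 100, plateau_scale = 260,
    supra_optimal_ca = 1900, supra_decline = 0.01,
    delay_min = 14, delay_range = 40, delay_scale = 500,
    rate_min = 0.05, rate_per_ca = 1e-4, seed = 1) {
  stopifnot(inherits(true_cu, "chill_unit_model"))
  if (plateau_max < 0 || plateau_max > 100) stop("plateau_max must be in [0, 100]")
  if (delay_min < 0 || delay_range < 0) stop("delays must be >= 0")
  if (rate_min <= 0) stop("rate_min must be positive")
  if (rate_per_ca < 0) stop("rate_per_ca must be >= 0")
  if (plateau_scale <= 0 || delay_scale <= 0) stop("scales must be positive")
  if (n_buds <= 0 || replicates <= 0) stop("n_buds and replicates must be positive")
  if (any(durations < 0)) stop("durations must be >= 0")
  structure(list(true_cu = true_cu, temperatures = temperatures,
                 durations = durations, n_buds = n_buds,
                 replicates = replicates, n_warm_days = n_warm_days,
                 plateau_max = plateau_max, plateau_scale = plateau_scale,
                 supra_optimal_ca = supra_optimal_ca,
                 supra_decline = supra_decline,
                 delay_min = delay_min, delay_range = delay_range,
                 delay_scale = delay_scale, rate_min = rate_min,
                 rate_per_ca = rate_per_ca, seed = seed),
            class = "sprouting_sim_config")
}

#' Plateau and delay functions of the sprouting simulator
#'
#' `plateau_ca()` is the expected final sprouting percentage at chilling
#' accumulation `ca`; it rises to saturation and, beyond the supra-optimal
#' accumulation, declines linearly (unimodal in Ca). `delay_ca()` is the
#' expected first-emergence warming day, decreasing in `ca`.
#'
#' @param ca Chilling accumulation(s), Ca >= 0.
#' @param config A [sprouting_sim_config()].
#' @return Percent in \[0, 100\] (plateau) or days (delay).
#' @export
plateau_ca <- function(ca, config) {
  stopifnot(inherits(config, "sprouting_sim_config"))
  p <- config$plateau_max * (1 - exp(-ca / config$plateau_scale))
  over <- ca > config$supra_optimal_ca
  p[over] <- p[over] - config$supra_decline * (ca[over] - config$supra_optimal_ca)
  clamp(p, 0, 100)
}

#' @rdname plateau_ca
#' @export
delay_ca <- function(ca, config) {
  stopifnot(inherits(config, "sprouting_sim_config"))
  config$delay_min + config$delay_range * exp(-ca / config$delay_scale)
}

#' @rdname plateau_ca
#' @export
rate_ca <- function(ca, config) {
  stopifnot(inherits(config, "sprouting_sim_config"))
  config$rate_min + config$rate_per_ca * ca
}

#' Simulate a replicated sprouting experiment
#'
#' Draws one experiment under the generating process described in
#' [sprouting_sim_config()]. Temperatures outside the generating model's
#' effective range (below 0 deg C or above its upper limit) contribute 0 Ca
#' and therefore yield flat curves; cumulative counts are non-decreasing by
#' construction.
#'
#' @param config A [sprouting_sim_config()].
#' @return A [sprouting_experiment()].
#' @export
simulate_sprouting <- function(config) {
  stopifnot(inherits(config, "sprouting_sim_config"))
  with_seed(config$seed, {
    days <- seq_len(config$n_warm_days)
    rows <- vector("list",
                   length(config$temperatures) * length(config$durations) *
                     config$replicates)
    i <- 0L
    for (tt in config$temperatures) {
      cu <- suppressWarnings(cu_value(config$true_cu, tt))
      for (dur in config$durations) {
        ca <- cu * 24 * dur
        p <- plateau_ca(ca, config) / 100
        dl <- delay_ca(ca, config)
        rt <- rate_ca(ca, config)
        for (rep_i in seq_len(config$replicates)) {
          i <- i + 1L
          sprouter <- stats::runif(config$n_buds) < p
          n_spr <- sum(sprouter)
          counts <- integer(config$n_warm_days)
          if (n_spr > 0) {
            day_spr <- ceiling(dl + stats::rlogis(n_spr) / rt)
            day_spr <- pmax(day_spr, 1)
            counts <- vapply(days, function(d) sum(day_spr <= d), 0L)
          }
          rows[[i]] <- data.frame(
            temperature = tt, chilling_days = dur, replicate = rep_i,
            n_buds = config$n_buds, day = days, sprouted = counts)
        }
      }
    }
    sprouting_experiment(do.call(rbind, rows))
  })
}
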