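test_that("rising-phase slope matches exact lines and flags flat curves", {
  # exact line over the rising window: days 3..5 rise 10%/day
  sl <- curve_slope(make_curve(c(0, 0, 10, 20, 30)))
  expect_equal(sl$slope, 10)
  expect_false(sl$no_emergence)
  expect_equal(sl$window, c(3, 5))

  flat <- curve_slope(make_curve(rep(0, 10)))
  expect_equal(flat$slope, 0)
  expect_true(flat$no_emergence)

  # one-day jump to the max: last pre-emergence day anchors the slope
  jump <- curve_slope(make_curve(c(0, 0, 40, 40, 40)))
  expect_equal(jump$slope, 40)

  # emergence already on day 1: implied 0% at day 0
  early <- curve_slope(make_curve(c(30, 30, 30)))
  expect_equal(early$slope, 30)
})

test_that("OLS rising-phase slope tracks the curve's maximum derivative", {
  # dense noise-free logistic curve: max derivative = rate * plateau / 4,
  # computed here by numerical differentiation as the independent check
  plateau <- 80; rate <- 0.5; delay <- 20; n_buds <- 20
  grid <- seq(1, 70, by = 0.01)
  dense <- plateau * stats::plogis(rate * (grid - delay))
  max_deriv <- max(diff(dense) / diff(grid))
  expect_equal(max_deriv, rate * plateau / 4, tolerance = 1e-4)
  # counted curve as recorded from 20 buds: zeros before first emergence
  day <- 1:70
  pct <- 100 * floor(n_buds * plateau *
                       stats::plogis(rate * (day - delay)) / 100) / n_buds
  sl <- curve_slope(make_curve(pct, day))$slope
  # OLS over the rising window averages the derivative, so it sits below
  # the logistic peak but on the same scale
  expect_gt(sl, 0.5 * max_deriv)
  expect_lt(sl, max_deriv)
})

test_that("chill units are slope ratios with the reference fixed at 1", {
  exp <- linear_experiment(list(`0` = 4, `4` = 4.332, `6` = 4.236))
  tab <- chill_unit_table(exp, reference_temperature = 0)
  expect_equal(tab$chill_unit[tab$temperature == 0], 1)
  expect_equal(tab$chill_unit[tab$temperature == 4], 1.083, tolerance = 1e-9)
  expect_equal(tab$chill_unit[tab$temperature == 6], 1.059, tolerance = 1e-9)
})

test_that("chill units are invariant to uniform count rescaling", {
  cfg <- sprouting_sim_config(temperatures = c(0, 2, 6), durations = c(15, 52),
                              n_warm_days = 50, seed = 11)
  exp <- simulate_sprouting(cfg)
  tab1 <- chill_unit_table(exp)
  doubled <- as.data.frame(exp)
  doubled$sprouted <- 2 * doubled$sprouted
  doubled$n_buds <- 2 * doubled$n_buds
  tab2 <- chill_unit_table(sprouting_experiment(doubled))
  expect_equal(tab1$chill_unit, tab2$chill_unit, tolerance = 1e-12)

  same <- linear_experiment(list(`0` = 3, `4` = 3, `8` = 3))
  expect_true(all(chill_unit_table(same)$chill_unit == 1))
})

test_that("chill-unit table requires a usable reference temperature", {
  exp <- linear_experiment(list(`0` = 4, `4` = 4.332))
  expect_error(chill_unit_table(exp, reference_temperature = 2),
               "not present")
  rec <- rbind(
    data.frame(temperature = 0, chilling_days = 30, replicate = 1,
               n_buds = 20, day = 1:5, sprouted = 0L),
    data.frame(temperature = 4, chilling_days = 30, replicate = 1,
               n_buds = 20, day = 1:5, sprouted = c(0L, 1L, 2L, 3L, 4L)))
  expect_error(chill_unit_table(sprouting_experiment(rec)),
               "reference temperature shows no emergence")
})

test_that("quadratic fit recovers exact generating coefficients", {
  m <- paper_cu_model()
  temps <- c(0, 2, 4, 6, 8, 10)
  tab <- structure(
    data.frame(temperature = temps,
               mean_slope = cu_value(m, temps) * 4,
               chill_unit = cu_value(m, temps),
               no_emergence = FALSE),
    class = c("chill_unit_table", "data.frame"), reference_temperature = 0)
  # exact data: lm warns that the perfect-fit summary is unreliable
  fit <- suppressWarnings(fit_cu_model(tab))
  expect_equal(fit$a, m$a, tolerance = 1e-6)
  expect_equal(fit$b, m$b, tolerance = 1e-6)
  expect_equal(fit$c, m$c, tolerance = 1e-6)
  expect_gt(fit$r_squared, 1 - 1e-9)
})

test_that("quadratic fit recovers noisy coefficients to a noise-scaled bound", {
  m <- paper_cu_model()
  temps <- c(0, 2, 4, 6, 8, 10)
  sd_noise <- 0.02
  errs <- t(sapply(1:50, function(s) {
    set.seed(s)
    tab <- structure(
      data.frame(temperature = temps, mean_slope = 1,
                 chill_unit = cu_value(m, temps) + rnorm(6, 0, sd_noise),
                 no_emergence = FALSE),
      class = c("chill_unit_table", "data.frame"), reference_temperature = 0)
    fit <- fit_cu_model(tab)
    abs(c(fit$a - m$a, fit$b - m$b, fit$c - m$c))
  }))
  # OLS coefficient standard errors for this design from (X'X)^-1 sigma^2:
  # a 0.00082, b 0.0085, c 0.018; mean absolute error must sit below 3 SE
  expect_lt(mean(errs[, 1]), 3 * 0.00082)
  expect_lt(mean(errs[, 2]), 3 * 0.0085)
  expect_lt(mean(errs[, 3]), 3 * 0.018)
})

test_that("degenerate chill-unit fits are rejected", {
  up <- structure(
    data.frame(temperature = c(0, 2, 4, 6), mean_slope = 1,
               chill_unit = c(1, 1.1, 1.4, 1.9), no_emergence = FALSE),
    class = c("chill_unit_table", "data.frame"), reference_temperature = 0)
  expect_error(fit_cu_model(up), "no interior optimum")
  two <- up[1:2, ]
  class(two) <- class(up)
  expect_error(fit_cu_model(two), "underdetermined")
  expect_error(chill_unit_model(0.1, 1, 1), "no interior optimum")
})

test_that("model evaluation clamps outside the effective range", {
  m <- paper_cu_model()
  expect_equal(cu_value(m, 2), 1.1142)  # -0.0154*4 + 0.0916*2 + 0.9926
  expect_equal(cu_value(m, 12), 0)
  expect_equal(cu_value(m, optimum_temperature(m)), cu_max(m),
               tolerance = 1e-12)
  expect_lt(abs(cu_value(m, upper_limit(m))), 1e-9)
  expect_warning(v <- cu_value(m, -2), "below 0")
  expect_equal(suppressWarnings(cu_value(m, -2)), 0)

  sym <- chill_unit_model(-1, 0, 1)
  expect_equal(optimum_temperature(sym), 0)
  expect_equal(upper_limit(sym), 1)
  expect_equal(cu_max(sym), 1)
})

test_that("simulated experiments recover the generating optimum temperature", {
  # full treatment design: 9 temperatures x 12 durations x 3 reps x 20 buds
  fits <- sapply(1:5, function(s) {
    cfg <- sprouting_sim_config(seed = s)
    fit <- fit_cu_model(chill_unit_table(simulate_sprouting(cfg)))
    optimum_temperature(fit)
  })
  truth <- optimum_temperature(sprouting_sim_config()$true_cu)
  expect_true(all(abs(fits - truth) <= 0.6))
})
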