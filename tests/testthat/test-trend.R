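# Logistic occurrence trends, Mann-Kendall, stability and group responses.

test_that("logistic trend recovers generating coefficients and handles null
           data", {
  a <- -304.15; b <- 0.15148
  set.seed(9)
  years <- 1901:2100
  y <- rbinom(200, 1, plogis(a + b * years))
  fit <- fit_logistic_trend(years, y)
  expect_lt(abs(fit$b - b) / b, 0.10)
  expect_false(fit$separation)

  # constant-probability data: deviance reduction is a null chi-square(1) draw
  set.seed(10)
  y0 <- rbinom(40, 1, 0.5)
  fit0 <- fit_logistic_trend(1971:2010, y0)
  expect_lt(fit0$deviance_reduction, qchisq(0.999, df = 1))
  # perfectly alternating outcomes: slope near zero
  fit_alt <- fit_logistic_trend(1971:2010, rep(c(0, 1), 20))
  expect_lt(abs(fit_alt$b), 0.02)
  # single-class outcomes are not estimable
  expect_error(fit_logistic_trend(1991:2010, rep(1, 20)), "single class")
  # C/W coding accepted
  fit_cw <- fit_logistic_trend(1971:2010, rep(c("C", "W"), 20))
  expect_equal(fit_cw$b, fit_alt$b)
})

test_that("complete separation is flagged, not reported as converged", {
  years <- 1981:2010
  y <- as.integer(years >= 1996)
  fit <- suppressWarnings(fit_logistic_trend(years, y))
  expect_true(fit$separation)
  expect_false(fit$converged)
})

test_that("warm-probability evaluation matches the logistic form", {
  expect_equal(predict_warm_probability(0, 0, 1999), 0.5)
  expect_equal(predict_warm_probability(-304.15, 0.15148, 2010),
               plogis(-304.15 + 0.15148 * 2010))
  # strictly increasing in year for positive slope
  p <- predict_warm_probability(-304.15, 0.15148, 1970:2030)
  expect_true(all(diff(p) > 0))
  expect_error(predict_warm_probability(NA, 1, 2000))
})

test_that("Mann-Kendall: exact extremes, brute-force agreement, monotone
           invariance", {
  expect_equal(mann_kendall(1:10)$tau, 1)
  expect_equal(mann_kendall(10:1)$tau, -1)
  set.seed(14)
  for (i in 1:25) {
    x <- sample(0:4, sample(4:10, 1), replace = TRUE)
    if (length(unique(x)) == 1) next
    got <- mann_kendall(x)
    want <- oracle_kendall_tau(x)
    expect_equal(got$S, want$S)
    expect_equal(got$tau, want$tau)
  }
  # invariance under strictly monotone transforms
  set.seed(15)
  x <- rnorm(20)
  expect_equal(mann_kendall(x)$tau, mann_kendall(exp(x))$tau)
  expect_equal(mann_kendall(x)$tau, mann_kendall(x^3 + 5 * x)$tau)
  expect_error(mann_kendall(rep(2, 8)), "undefined")
  expect_error(mann_kendall(c(1, 2, 3)), "at least 4")
})

test_that("freshwater density peaks near 3.98 degC", {
  t <- seq(0, 10, by = 0.01)
  expect_equal(t[which.max(water_density(t))], 3.98, tolerance = 0.02)
  expect_true(all(diff(water_density(seq(5, 30, 0.5))) < 0))
})

test_that("Brunt-Vaisala frequency: isothermal zero, stable stratification,
           finite-difference oracle", {
  z <- c(0, 2, 4, 6, 8, 10, 12, 15)
  iso <- brunt_vaisala(z, rep(12, 8))
  expect_equal(iso$mean_frequency, 0)
  expect_false(iso$clipped)

  # warm epilimnion over 4 degC deep water: stable everywhere below surface
  temps <- 4 + 16 * exp(-z / 4)
  strat <- brunt_vaisala(z, temps)
  expect_true(all(strat$n_squared > 0))
  expect_gt(strat$mean_frequency, 0)

  # N^2 matches an independent finite-difference computation on densities
  two_layer <- c(20, 20, 19.5, 12, 6, 5, 4.5, 4.2)
  got <- brunt_vaisala(z, two_layer)
  want <- oracle_n_squared(z, water_density(two_layer))
  expect_equal(got$n_squared, want, tolerance = 1e-10)

  # invariant to uniform depth translation
  shifted <- brunt_vaisala(z + 100, two_layer, depth_range = c(100, 115))
  expect_equal(shifted$n_squared, got$n_squared, tolerance = 1e-12)

  # input handling
  expect_error(brunt_vaisala(c(0, 2, 2, 5), c(10, 9, 8, 7)), "duplicate")
  expect_warning(brunt_vaisala(c(5, 0, 10, 15), c(10, 12, 6, 5)), "sorting")
  expect_error(brunt_vaisala(c(0, 5), c(10, 8)), "3 depths")
})

test_that("response-by-code splits, tests and summarises the groups", {
  years <- 2001:2020
  codes <- matrix(rep(c("C", "W"), each = 4 * 10), ncol = 4, byrow = TRUE)
  grid <- cw_grid(years, codes)
  # clearly separated groups: U test highly significant
  set.seed(17)
  resp <- data.frame(year = years,
                     value = c(rnorm(10, 0, 0.5), rnorm(10, 5, 0.5)))
  r <- response_by_code(resp, grid, phase = 3)
  expect_true(r$tested)
  expect_lt(r$u_p, 0.001)
  expect_length(r$group_C, 10)
  expect_lt(r$summary_C[["q50"]], r$summary_W[["q50"]])
  # identical values in both groups: p = 1
  resp2 <- data.frame(year = years, value = rep(1:10, 2))
  r2 <- response_by_code(resp2, grid, phase = 1)
  expect_equal(r2$u_p, 1)
  # U statistic matches explicit pair counting for small groups
  set.seed(18)
  small_years <- 2001:2014
  small_grid <- cw_grid(small_years,
                        matrix(rep(rep(c("C", "W"), c(7, 7)), 4), ncol = 4))
  vals <- round(rnorm(14), 1)
  r3 <- response_by_code(data.frame(year = small_years, value = vals),
                         small_grid, phase = 2)
  expect_equal(r3$u_statistic, oracle_u_statistic(vals[1:7], vals[8:14]))
  # small groups: tests suppressed, summaries kept
  lop_grid <- cw_grid(years, matrix(rep(rep(c("C", "W"), c(2, 18)), 4),
                                    ncol = 4))
  expect_warning(r4 <- response_by_code(resp, lop_grid, phase = 1), "fewer")
  expect_false(r4$tested)
  expect_false(anyNA(r4$summary_W))
})
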