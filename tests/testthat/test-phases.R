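# Daily interpolation, phase detection and window means.

test_that("interpolation is linear through knots and respects the gap limit", {
  obs <- data.frame(
    date = as.Date("2001-01-01") + c(99, 103, 150, 200) - 1,
    depth_m = 3,
    temp_c = c(10, 14, 12, 18)
  )
  # second depth so the series is complete
  obs <- rbind(obs, transform(obs, depth_m = 10, temp_c = c(4, 4.5, 5, 6)))
  prof <- profile_series(obs, "t")
  daily <- interpolate_daily(prof, max_gap_days = 21)
  at <- function(doy, z) daily$temp_c[daily$day_of_year == doy &
                                        daily$depth_m == z]
  # midpoint of a linear segment
  expect_equal(at(101, 3), 12)
  # observation days reproduced exactly
  expect_equal(at(99, 3), 10)
  expect_equal(at(103, 3), 14)
  expect_equal(at(150, 3), 12)
  # the 47-day and 50-day gaps are not bridged
  expect_true(all(is.na(at(120, 3))))
  expect_true(all(is.na(at(175, 3))))
  # but interpolated flags are set inside bridged spans
  expect_true(daily$interpolated[daily$day_of_year == 101 & daily$depth_m == 3])
})

test_that("weekly subsampling of a smooth curve reconstructs within the
           second-derivative bound", {
  doy <- 1:210
  truth <- 10 + 8 * sin(2 * pi * (doy - 60) / 365)
  obs_days <- seq(1, 210, by = 7)
  obs <- data.frame(
    date = as.Date("2001-01-01") + obs_days - 1,
    depth_m = 3, temp_c = truth[obs_days]
  )
  obs <- rbind(obs, transform(obs, depth_m = 10))
  daily <- interpolate_daily(profile_series(obs, "sin"))
  rec <- daily$temp_c[daily$depth_m == 3]
  days <- daily$day_of_year[daily$depth_m == 3]
  # |f''| <= 8 (2 pi / 365)^2; linear interpolation error <= max|f''| h^2 / 8
  bound <- 8 * (2 * pi / 365)^2 * 7^2 / 8
  expect_lt(max(abs(rec - truth[days])), bound + 1e-12)
})

test_that("interpolation warns and skips single-observation depth-years", {
  obs <- data.frame(
    date = as.Date(c("2002-03-01", "2002-03-08", "2002-03-01")),
    depth_m = c(3, 3, 10),
    temp_c = c(5, 6, 4)
  )
  prof <- profile_series(obs, "short")
  expect_warning(daily <- interpolate_daily(prof), "< 2 observations")
  expect_false(10 %in% daily$depth_m)
})

test_that("phase-1 end: threshold crossing and ice-off precedence", {
  # constant 5 degC: already above 3 degC on day 1
  d1 <- make_daily_series(2000, list(`3` = rep(5, 181), `10` = rep(4, 181)))
  expect_equal(detect_phase1_end(d1, 2000), 1)
  # upward crossing on day 70
  t3 <- c(rep(2, 69), seq(3.5, 12, length.out = 112))
  d2 <- make_daily_series(2000, list(`3` = t3, `10` = rep(4, 181)))
  expect_equal(detect_phase1_end(d2, 2000), 70)
  # provided ice-off day wins over the temperature criterion
  expect_equal(detect_phase1_end(d2, 2000, ice_off_day = 60), 60)
  # never met by 30 June -> missing with warning
  d3 <- make_daily_series(2000, list(`3` = rep(2, 181), `10` = rep(4, 181)))
  expect_warning(r <- detect_phase1_end(d3, 2000), "not detected")
  expect_true(is.na(r))
})

test_that("phase-2 start requires the whole 0-10 m column at 4 degC", {
  # isothermal 4.0 from day 91; colder surface before
  t3 <- c(rep(3, 90), rep(4, 91))
  t10 <- c(rep(4, 90), rep(4, 91))
  d <- make_daily_series(2000, list(`3` = t3, `10` = t10))
  expect_equal(detect_phase2_start(d, 2000), 91)
  # warm surface over a 3.5 degC deep layer does not qualify
  d2 <- make_daily_series(2000, list(`3` = rep(6, 181), `10` = rep(3.5, 181)))
  expect_warning(r <- detect_phase2_start(d2, 2000), "not detected")
  expect_true(is.na(r))
  # missing deep coverage is flagged
  d3 <- make_daily_series(2000, list(`3` = rep(5, 181)))
  expect_warning(r3 <- detect_phase2_start(d3, 2000), "depth coverage")
  expect_true(is.na(r3))
})

test_that("phase-3 start uses the first crossing and ignores later dips", {
  t3 <- c(rep(5, 120), 11, 11, 9.5, 9.5, rep(12, 88))
  d <- make_daily_series(2000, list(`3` = t3, `10` = rep(6, 212)))
  expect_equal(detect_phase3_start(d, 2000), 121)
  # dips after the first crossing do not move it
  expect_equal(detect_phase3_start(d, 2000, after_day = 100), 121)
  # searching after a later phase-2 day skips earlier crossings
  expect_equal(detect_phase3_start(d, 2000, after_day = 124), 125)
})

test_that("phase windows follow the half-up shifted calendar", {
  w0 <- phase_windows(0)
  expect_equal(w0$start_day, c(1, 91, 121, 182))
  expect_equal(w0$end_day, c(74, 91, 151, 212))
  # +19.5 rounds half-up to +20
  w <- phase_windows(19.5)
  expect_equal(w$start_day[2], 111)
  expect_equal(w$start_day[1], 1)   # phase 1 always starts 1 January
  expect_equal(w$end_day[1], 94)
  # -7.1 rounds to -7
  expect_equal(phase_windows(-7.1)$start_day[4], 175)
  expect_error(phase_windows(45), "40")
})

test_that("phase means: constants, ramps and redundant-observation
           invariance", {
  t3 <- rep(13, 365)
  t3[121:151] <- seq(10, 16, length.out = 31)
  d <- make_daily_series(2000, list(`3` = t3, `10` = rep(7, 365)))
  m <- phase_mean_temperatures(d, 2000)
  expect_equal(m$phase1, 13)
  expect_equal(m$phase2, 7)        # 10 m reading on day 91
  expect_equal(m$phase3, 13)       # midpoint of the 10..16 ramp
  expect_equal(m$phase4, 13)

  # adding collinear intermediate observations does not change the means
  base_days <- seq(1, 365, by = 8)
  line <- function(doy) 4 + doy * 0.04
  obs1 <- data.frame(date = as.Date("2003-01-01") + base_days - 1,
                     depth_m = 3, temp_c = line(base_days))
  obs1 <- rbind(obs1, transform(obs1, temp_c = temp_c - 1, depth_m = 10))
  extra_days <- seq(4, 364, by = 16)
  obs2 <- rbind(obs1, data.frame(
    date = as.Date("2003-01-01") + extra_days - 1,
    depth_m = 3, temp_c = line(extra_days)
  ))
  m1 <- phase_mean_temperatures(interpolate_daily(profile_series(obs1)), 2003)
  m2 <- phase_mean_temperatures(interpolate_daily(profile_series(obs2)), 2003)
  expect_equal(m1$phase3, m2$phase3, tolerance = 1e-12)
  expect_equal(m1$phase4, m2$phase4, tolerance = 1e-12)
})

test_that("phase-2 fallback substitutes a nearby day and flags it", {
  t10 <- rep(6, 365)
  t10[88:93] <- NA    # evaluation day 91 and neighbours missing
  t10[94] <- 6.5
  d <- make_daily_series(2000, list(`3` = rep(8, 365), `10` = t10))
  expect_warning(m <- phase_mean_temperatures(d, 2000), "substituted")
  expect_equal(m$phase2, 6.5)
  expect_true(m$phase2_substituted)
  # low coverage leaves the mean missing
  t3 <- rep(13, 365); t3[121:145] <- NA
  d2 <- make_daily_series(2000, list(`3` = t3, `10` = rep(6, 365)))
  expect_warning(m2 <- phase_mean_temperatures(d2, 2000), "coverage")
  expect_true(is.na(m2$phase3))
})

test_that("detected timings are ordered on synthetic lakes", {
  for (lat in c(47.33, 50.733, 55)) {
    sim <- generate_lake(lake_scenario(latitude_deg = lat, years = 3, seed = 5))
    tab <- suppressWarnings(phase_table(interpolate_daily(sim$profiles),
                                        shift_days = sim$truth$shift_days))
    with(tab, {
      expect_true(all(phase1_end_day <= phase2_start_day, na.rm = TRUE))
      expect_true(all(phase2_start_day <= phase3_start_day, na.rm = TRUE))
      expect_true(all(phase3_start_day <= phase4_start_day, na.rm = TRUE))
    })
  }
})
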