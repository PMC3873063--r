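# Synthetic dimictic-lake generator with analytically known ground truth.
#
# The epilimnion (3 m) is driven by a logistic function of cumulative
# clear-sky radiation at the scenario latitude -- the same radiation model
# used for the latitudinal date transfer -- with per-year warm/cold offsets,
# a winter floor, and an autumn cool-down outside the analysis windows.
# The deep water tracks the column between 4 degC (the maximum-density
# floor under winter inverse stratification) and a summer hypolimnion cap,
# so the lake passes through the full dimictic cycle: inverse winter
# stratification, 4 degC homothermy at spring overturn, a near-homothermal
# warming column, a two-layer summer structure with a logistic thermocline,
# and fall cooling. Ground truth (phase timings, phase means, CW codes) is
# derived from the noise-free closed-form curves, never from the detection
# code.

#' Define a synthetic dimictic-lake scenario
#'
#' Default sigmoid parameters are calibrated so that the noise-free
#' reference-latitude lake (50.73 degrees N) crosses 4 degC homothermy on
#' day 91 and 10 degC at 3 m on day 121, the long-term mean phase starts of
#' the reference system; the midpoint and scale are therefore expressed in
#' cumulative *clear-sky* radiation units.
#'
#' @param latitude_deg latitude of the synthetic lake, degrees north.
#' @param years number of simulated years.
#' @param start_year first calendar year.
#' @param depth_grid observed depths in m (must include 3 and 10).
#' @param sigmoid_asymptote_c summer saturation temperature A, degC.
#' @param sigmoid_midpoint_kj_cm2 cumulative clear-sky radiation at the
#'   sigmoid inflection, kJ cm^-2.
#' @param sigmoid_scale_kj_cm2 sigmoid rise scale, kJ cm^-2.
#' @param winter_min_temp_c floor of the 3 m series in winter, degC.
#' @param thermocline_depth_m depth of the summer thermocline, m.
#' @param thermocline_width_m width of the logistic depth transition, m.
#' @param hypolimnion_temp_c summer hypolimnion temperature, degC: the cap up
#'   to which the deep water follows the warming column before the summer
#'   two-layer structure locks in. In winter the deep water sits at 4 degC
#'   (maximum freshwater density) regardless.
#' @param year_offsets_c per-year temperature offsets (degC) added to the
#'   epilimnion curve; length \code{years}.
#' @param observation_noise_sd_c s.d. of Gaussian observation noise, degC.
#' @param sampling_interval_days days between simulated field campaigns.
#' @param turbidity Linke turbidity of the radiation forcing.
#' @param seed integer seed fixing all randomness.
#' @return a list of class \code{lake_scenario}.
#' @export
lake_scenario <- function(latitude_deg = 50.733,
                          years = 20,
                          start_year = 1990,
                          depth_grid = c(0, 3, 5, 8, 10, 12, 15, 20),
                          sigmoid_asymptote_c = 21.048,
                          sigmoid_midpoint_kj_cm2 = 179.2,
                          sigmoid_scale_kj_cm2 = 54.5,
                          winter_min_temp_c = 1,
                          thermocline_depth_m = 8,
                          thermocline_width_m = 1.5,
                          hypolimnion_temp_c = 6,
                          year_offsets_c = rep(0, years),
                          observation_noise_sd_c = 0,
                          sampling_interval_days = 1,
                          turbidity = 2,
                          seed = 1) {
  stopifnot(
    length(year_offsets_c) == years,
    all(is.finite(year_offsets_c)),
    is.finite(observation_noise_sd_c), observation_noise_sd_c >= 0,
    all(diff(depth_grid) > 0),
    sampling_interval_days >= 1
  )
  if (!(3 %in% depth_grid) || !(10 %in% depth_grid)) {
    stop("depth_grid must include 3 m and 10 m", call. = FALSE)
  }
  structure(as.list(environment()), class = "lake_scenario")
}

# 365-day day-of-year -> calendar Date (skipping 29 February in leap years)
.doy_to_date <- function(year, doy) {
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  as.Date(sprintf("%d-01-01", year)) + (doy - 1) + (leap & doy >= 60)
}

#' Generate a synthetic lake with ground truth
#'
#' @param scenario a \code{\link{lake_scenario}}.
#' @param reference_latitude latitude (degrees N) against which the
#'   latitudinal window shift is computed; default the reference system at
#'   50.733 degrees N.
#' @param thresholds \code{\link{threshold_set}} used for the ground-truth CW
#'   codes; default the constant lake profile (3, 4, 14, 20 degC).
#' @return a list: \code{profiles} (a \code{\link{profile_series}} of
#'   subsampled noisy observations) and \code{truth} with \code{timings},
#'   \code{means}, \code{codes} (\code{\link{cw_grid}}), \code{shift_days},
#'   and the noise-free 3 m curves (\code{daily_3m}, a 365 x years matrix).
#' @export
generate_lake <- function(scenario,
                          reference_latitude = 50.733,
                          thresholds = threshold_profile("lake")) {
  stopifnot(inherits(scenario, "lake_scenario"))
  sc <- scenario
  set.seed(sc$seed)
  curve <- radiation_curve(sc$latitude_deg, sc$turbidity)
  cum <- curve$cumulative_kj_cm2
  shift <- if (isTRUE(all.equal(sc$latitude_deg, reference_latitude))) 0 else
    latitudinal_shift_days(reference_latitude, sc$latitude_deg)$mean_shift_days

  epi_base <- sc$sigmoid_asymptote_c /
    (1 + exp(-(cum - sc$sigmoid_midpoint_kj_cm2) / sc$sigmoid_scale_kj_cm2))

  # logistic depth weight, normalised so the 3 m horizon carries the driver
  w <- function(z) {
    stats::plogis((sc$thermocline_depth_m - z) / sc$thermocline_width_m) /
      stats::plogis((sc$thermocline_depth_m - 3) / sc$thermocline_width_m)
  }
  w_grid <- w(sc$depth_grid)
  w10 <- w(10)

  years <- sc$start_year + seq_len(sc$years) - 1
  obs_days <- seq(1, 365, by = sc$sampling_interval_days)
  daily_3m <- matrix(NA_real_, 365, sc$years,
                     dimnames = list(NULL, years))
  timings <- list(); means <- list(); codes <- list(); obs <- list()
  autumn_start <- 243L  # analysis windows end by late August; cool down after
  r_shift <- as.integer(floor(shift + 0.5))
  win <- phase_windows(shift)

  for (i in seq_len(sc$years)) {
    drv <- epi_base + sc$year_offsets_c[i]
    tail_idx <- (autumn_start + 1):365
    drv[tail_idx] <- sc$winter_min_temp_c +
      (drv[autumn_start] - sc$winter_min_temp_c) *
      (365 - tail_idx) / (365 - autumn_start)
    drv <- pmax(drv, sc$winter_min_temp_c)
    daily_3m[, i] <- drv

    # ground truth from the noise-free curve
    p1 <- which(drv[1:181] > 3)[1]
    p2 <- which(drv[1:181] >= 4)[1]
    p3 <- if (is.na(p2)) NA_integer_ else {
      h <- which(drv[1:212] > 10); h <- h[h >= p2]
      if (length(h)) h[1] else NA_integer_
    }
    timings[[i]] <- data.frame(
      year = years[i], phase1_end_day = p1, phase2_start_day = p2,
      phase3_start_day = p3, phase4_start_day = 182L + r_shift
    )
    # deep water: 4 degC maximum-density floor in winter, follows the
    # column through overturn, capped at the summer hypolimnion temperature
    deep <- pmin(pmax(drv, 4), sc$hypolimnion_temp_c)
    m <- c(
      mean(drv[win$start_day[1]:win$end_day[1]]),
      deep[win$start_day[2]] + (drv[win$start_day[2]] - deep[win$start_day[2]]) * w10,
      mean(drv[win$start_day[3]:win$end_day[3]]),
      mean(drv[win$start_day[4]:win$end_day[4]])
    )
    means[[i]] <- data.frame(year = years[i], phase1 = m[1], phase2 = m[2],
                             phase3 = m[3], phase4 = m[4])
    codes[[i]] <- classify_year(m, thresholds)

    # subsampled noisy observations over the full depth grid
    # tmat[z, t] = deep(t) + (drv(t) - deep(t)) * w(z)
    deep_obs <- matrix(deep[obs_days], nrow = length(w_grid),
                       ncol = length(obs_days), byrow = TRUE)
    drv_obs <- matrix(drv[obs_days], nrow = length(w_grid),
                      ncol = length(obs_days), byrow = TRUE)
    tmat <- deep_obs + (drv_obs - deep_obs) * w_grid
    if (sc$observation_noise_sd_c > 0) {
      tmat <- tmat + stats::rnorm(length(tmat), 0, sc$observation_noise_sd_c)
    }
    tmat <- pmin(pmax(tmat, -2), 40)
    obs[[i]] <- data.frame(
      date = rep(.doy_to_date(years[i], obs_days), each = length(sc$depth_grid)),
      depth_m = rep(sc$depth_grid, times = length(obs_days)),
      temp_c = as.vector(tmat)
    )
  }

  profiles <- profile_series(do.call(rbind, obs),
                             site_id = sprintf("synthetic_%.2fN", sc$latitude_deg))
  truth <- list(
    timings = do.call(rbind, timings),
    means = do.call(rbind, means),
    codes = cw_grid(years, do.call(rbind, codes),
                    site_id = attr(profiles, "site_id")),
    shift_days = shift,
    daily_3m = daily_3m,
    cumulative_radiation = cum
  )
  list(profiles = profiles, truth = truth, scenario = sc)
}
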