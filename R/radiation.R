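# Clear-sky solar radiation and latitudinal transfer of phase timing.
#
# The daily clear-sky global radiation model is astronomical only: solar
# constant, orbital eccentricity, solar declination, hour-angle integration,
# beam extinction through a Linke-turbidity atmosphere, plus a simple
# clear-sky diffuse fraction. Cloud cover, humidity and altitude are outside
# the model by design; only the *relative* shape of the cumulative curve
# across latitude carries information for the date transfer.

SOLAR_CONSTANT_W_M2 <- 1367

# cache of radiation curves keyed by (latitude, turbidity); transfer_date is
# called repeatedly on the same few latitudes
.rad_cache <- new.env(parent = emptyenv())

#' Solar declination (radians) for a day of year
#'
#' Fourier-series approximation (Spencer 1971) on a 365-day calendar.
#'
#' @param day_of_year integer day of year, 1..365.
#' @return declination in radians.
#' @keywords internal
solar_declination <- function(day_of_year) {
  g <- 2 * pi * (day_of_year - 1) / 365
  0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.001480 * sin(3 * g)
}

# eccentricity correction of the solar "constant"
eccentricity_factor <- function(day_of_year) {
  1 + 0.033 * cos(2 * pi * day_of_year / 365)
}

# Kasten & Young (1989) relative optical air mass from solar elevation (rad)
relative_air_mass <- function(elevation_rad) {
  h_deg <- elevation_rad * 180 / pi
  1 / (sin(elevation_rad) + 0.50572 * (h_deg + 6.07995)^-1.6364)
}

# Rayleigh optical thickness at air mass m (Kasten 1996)
rayleigh_optical_depth <- function(m) {
  ifelse(
    m <= 20,
    1 / (6.6296 + 1.7513 * m - 0.1202 * m^2 + 0.0065 * m^3 - 0.00013 * m^4),
    1 / (10.4 + 0.718 * m)
  )
}

#' Instantaneous clear-sky global irradiance on a horizontal surface
#'
#' Beam component follows exponential extinction with the Linke turbidity
#' factor and relative optical air mass; the diffuse component uses the
#' Liu-Jordan clear-sky relation between diffuse and beam transmittance.
#'
#' @param elevation_rad solar elevation angle(s), radians.
#' @param day_of_year day of year (for the eccentricity correction).
#' @param turbidity Linke turbidity factor (dimensionless, >= 1).
#' @return irradiance in W m^-2 (0 when the sun is below the horizon).
#' @keywords internal
clear_sky_irradiance <- function(elevation_rad, day_of_year, turbidity) {
  up <- elevation_rad > 0
  g <- numeric(length(elevation_rad))
  if (!any(up)) return(g)
  h <- elevation_rad[up]
  e0 <- eccentricity_factor(day_of_year)
  m <- relative_air_mass(h)
  tau_b <- exp(-0.8662 * turbidity * m * rayleigh_optical_depth(m))
  extraterrestrial <- SOLAR_CONSTANT_W_M2 * e0 * sin(h)
  beam <- extraterrestrial * tau_b
  diffuse <- extraterrestrial * pmax(0.2710 - 0.2939 * tau_b, 0)
  g[up] <- beam + diffuse
  g
}

#' Daily clear-sky global radiation sum
#'
#' Integrates modelled cloudless global irradiance (direct + diffuse) over the
#' day by hour-angle quadrature and returns the daily energy sum.
#'
#' @param latitude_deg geographic latitude in degrees north (-66..66).
#' @param day_of_year day of year, 1..365 (vectorised). A 365-day calendar is
#'   used throughout; in leap years 29 February maps onto day 59.
#' @param turbidity Linke turbidity factor, >= 1. Default 2 (very clear
#'   atmosphere).
#' @param step_min integration time step in minutes (<= 5 recommended).
#' @return daily radiation sum(s) in kJ cm^-2 day^-1.
#' @examples
#' daily_clear_sky_radiation(50.73, 172)  # midsummer at the reference lake
#' @export
daily_clear_sky_radiation <- function(latitude_deg, day_of_year, turbidity = 2,
                                      step_min = 5) {
  stopifnot(length(latitude_deg) == 1, length(turbidity) == 1)
  if (!is.finite(latitude_deg) || abs(latitude_deg) > 66) {
    stop("latitude_deg must lie within -66..66 degrees", call. = FALSE)
  }
  if (any(!is.finite(day_of_year)) || any(day_of_year < 1) ||
      any(day_of_year > 365) || any(day_of_year != round(day_of_year))) {
    stop("day_of_year must be integer in 1..365", call. = FALSE)
  }
  if (!is.finite(turbidity) || turbidity < 1) {
    stop("turbidity must be >= 1", call. = FALSE)
  }
  phi <- latitude_deg * pi / 180
  dt_s <- step_min * 60
  n_steps <- ceiling(24 * 60 / step_min)
  # hour angle at step midpoints, symmetric about solar noon
  omega <- (seq_len(n_steps) - 0.5) / n_steps * 2 * pi - pi
  vapply(day_of_year, function(d) {
    decl <- solar_declination(d)
    sin_h <- sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(omega)
    g <- clear_sky_irradiance(asin(pmin(pmax(sin_h, -1), 1)), d, turbidity)
    sum(g) * dt_s * 1e-7  # J m^-2 -> kJ cm^-2
  }, numeric(1))
}

#' Clear-sky radiation curve for a latitude
#'
#' @inheritParams daily_clear_sky_radiation
#' @return a data frame of class \code{radiation_curve} with columns
#'   \code{day_of_year}, \code{daily_kj_cm2} and \code{cumulative_kj_cm2}
#'   (running sum from 1 January); attributes \code{latitude_deg} and
#'   \code{turbidity}.
#' @export
radiation_curve <- function(latitude_deg, turbidity = 2, step_min = 5) {
  key <- sprintf("%.6f|%.4f|%g", latitude_deg, turbidity, step_min)
  if (!is.null(.rad_cache[[key]])) return(.rad_cache[[key]])
  daily <- daily_clear_sky_radiation(latitude_deg, 1:365, turbidity, step_min)
  curve <- data.frame(
    day_of_year = 1:365,
    daily_kj_cm2 = daily,
    cumulative_kj_cm2 = cumsum(daily)
  )
  attr(curve, "latitude_deg") <- latitude_deg
  attr(curve, "turbidity") <- turbidity
  class(curve) <- c("radiation_curve", "data.frame")
  .rad_cache[[key]] <- curve
  curve
}

#' Cumulative clear-sky radiation from 1 January
#'
#' @inheritParams daily_clear_sky_radiation
#' @param up_to_day last day of year included in the sum, 1..365.
#' @return cumulative radiation in kJ cm^-2.
#' @export
cumulative_radiation <- function(latitude_deg, up_to_day, turbidity = 2) {
  if (any(up_to_day < 1) || any(up_to_day > 365) ||
      any(up_to_day != round(up_to_day))) {
    stop("up_to_day must be integer in 1..365", call. = FALSE)
  }
  curve <- radiation_curve(latitude_deg, turbidity)
  curve$cumulative_kj_cm2[up_to_day]
}

#' Transfer a day of year between latitudes by matching cumulative radiation
#'
#' Finds the day at the target latitude with the same cumulative clear-sky
#' radiation since 1 January as the reference day at the reference latitude.
#' The integer convention returns the first day whose cumulative sum meets or
#' exceeds the reference value; \code{interpolate = TRUE} returns a fractional
#' day by linear interpolation within that day.
#'
#' @param lat_ref,lat_target latitudes in degrees north. The transfer is
#'   validated for 45-66 degrees N during the spring half-year.
#' @param day_ref day of year at the reference latitude, 1..365.
#' @param turbidity Linke turbidity factor shared by both curves.
#' @param interpolate logical; return a fractional day instead of the integer
#'   ceiling day.
#' @return day of year at the target latitude (integer unless
#'   \code{interpolate}).
#' @examples
#' transfer_date(50.73, 121, 59.52)  # 1 May moved north to Lake Erken
#' @export
transfer_date <- function(lat_ref, day_ref, lat_target, turbidity = 2,
                          interpolate = FALSE) {
  if (day_ref < 1 || day_ref > 365 || day_ref != round(day_ref)) {
    stop("day_ref must be integer in 1..365", call. = FALSE)
  }
  target_value <- cumulative_radiation(lat_ref, day_ref, turbidity)
  curve <- radiation_curve(lat_target, turbidity)
  cum <- curve$cumulative_kj_cm2
  hits <- which(cum >= target_value)
  if (!length(hits)) {
    stop(sprintf(
      "cumulative radiation at latitude %.2f never reaches %.2f kJ cm-2 within day 365",
      lat_target, target_value
    ), call. = FALSE)
  }
  t_int <- hits[1]
  if (!interpolate) return(t_int)
  below <- if (t_int == 1) 0 else cum[t_int - 1]
  t_int - 1 + (target_value - below) / (cum[t_int] - below)
}

#' Mean latitudinal shift of phase-start days
#'
#' Transfers each reference phase-start day to the target latitude and
#' averages the resulting shifts into a single per-site offset, the quantity
#' applied downstream when phase windows are moved between sites.
#'
#' @param lat_ref reference latitude in degrees north.
#' @param lat_target target latitude in degrees north.
#' @param phase_start_days reference-site mean start days; default days 91 and
#'   121 (spring overturn and early thermal stratification).
#' @param turbidity Linke turbidity factor.
#' @param interpolate use fractional-day transfer (default; gives shifts at
#'   sub-day resolution).
#' @return a list with \code{per_day_shifts} (named by anchor day) and
#'   \code{mean_shift_days} (signed; positive = later at the target).
#' @export
latitudinal_shift_days <- function(lat_ref, lat_target,
                                   phase_start_days = c(91, 121),
                                   turbidity = 2, interpolate = TRUE) {
  shifts <- vapply(
    phase_start_days,
    function(d) transfer_date(lat_ref, d, lat_target, turbidity,
                              interpolate = interpolate) - d,
    numeric(1)
  )
  names(shifts) <- as.character(phase_start_days)
  list(per_day_shifts = shifts, mean_shift_days = mean(shifts))
}

#' Fit the sigmoid link between cumulative radiation and epilimnion temperature
#'
#' Least-squares fit of the three-parameter logistic
#' T = A / (1 + exp(-(x - x0) / s)) where x is radiation cumulated from
#' 1 January and T the epilimnion temperature. A is the saturation
#' temperature reached during summer stagnation (degrees C), x0 the cumulative
#' radiation at the inflection (kJ cm^-2) and s the rise scale (kJ cm^-2).
#'
#' @param cum_rad numeric vector of cumulative radiation values, kJ cm^-2.
#' @param temp numeric vector of matching temperatures, degrees C.
#' @return a list with \code{asymptote_c}, \code{midpoint_kj_cm2},
#'   \code{scale_kj_cm2}, \code{r_squared} and the underlying \code{fit}.
#' @export
fit_radiation_temperature_sigmoid <- function(cum_rad, temp) {
  ok <- is.finite(cum_rad) & is.finite(temp)
  cum_rad <- cum_rad[ok]; temp <- temp[ok]
  if (length(temp) < 10) {
    stop("need at least 10 paired observations", call. = FALSE)
  }
  if (stats::sd(temp) < 1e-8) {
    stop("temperature input is constant; sigmoid scale is unidentifiable",
         call. = FALSE)
  }
  df <- data.frame(x = cum_rad, y = temp)
  fit <- tryCatch(
    stats::nls(y ~ SSlogis(x, Asym, xmid, scal), data = df),
    error = function(e) {
      # self-starting fit can fail on short or noisy rises; retry with a
      # Levenberg-Marquardt fit from crude moment-based starts
      start <- list(Asym = max(temp), xmid = stats::median(cum_rad),
                    scal = diff(range(cum_rad)) / 4)
      tryCatch(
        minpack.lm::nlsLM(y ~ Asym / (1 + exp(-(x - xmid) / scal)),
                          data = df, start = start,
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e2) {
          stop(sprintf("sigmoid fit failed to converge: %s",
                       conditionMessage(e2)), call. = FALSE)
        }
      )
    }
  )
  co <- stats::coef(fit)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((temp - mean(temp))^2)
  list(
    asymptote_c = unname(co[["Asym"]]),
    midpoint_kj_cm2 = unname(co[["xmid"]]),
    scale_kj_cm2 = unname(co[["scal"]]),
    r_squared = 1 - ss_res / ss_tot,
    fit = fit
  )
}
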