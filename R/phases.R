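# Phase detection: daily interpolation of depth-resolved temperature
# profiles, detection of the four climate-sensitive phases of a dimictic
# year, and time-weighted phase-mean temperatures over latitude-shifted
# calendar windows.
#
# Phases: 1 inverse winter stratification (ends at ice-off or the 3 m
# temperature exceeding 3 degC), 2 spring overturn (first day of 4 degC
# homothermy over 0..deep_ref_depth), 3 early thermal stratification (3 m
# temperature exceeding 10 degC), 4 summer stagnation (fixed to July).

PHASE1_TEMP_C <- 3
PHASE2_TEMP_C <- 4
PHASE3_TEMP_C <- 10

# detection search window: January through June (365-day calendar)
SPRING_LAST_DAY <- 181

#' Day of year on a 365-day calendar
#'
#' 29 February is merged into day 59, so that day-of-year indices are
#' comparable across leap and common years and line up with the radiation
#' curves.
#'
#' @param date a \code{Date} vector.
#' @return integer day of year, 1..365.
#' @export
doy365 <- function(date) {
  stopifnot(inherits(date, "Date"))
  y <- as.integer(format(date, "%Y"))
  doy <- as.POSIXlt(date)$yday + 1L
  leap <- (y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0
  doy[leap & doy >= 60L] <- doy[leap & doy >= 60L] - 1L
  doy
}

#' Construct a depth-resolved temperature profile series
#'
#' @param data a data frame with columns \code{date} (Date or ISO-8601
#'   character), \code{depth_m} and \code{temp_c}.
#' @param site_id site identifier.
#' @param ice_off optional data frame \code{year}, \code{ice_off_date} of
#'   per-year ice-off dates.
#' @return the validated data frame with class \code{profile_series} and
#'   attributes \code{site_id} and \code{ice_off}.
#' @export
profile_series <- function(data, site_id = "site", ice_off = NULL) {
  stopifnot(is.data.frame(data))
  need <- c("date", "depth_m", "temp_c")
  if (!all(need %in% names(data))) {
    stop("profile data must have columns date, depth_m, temp_c", call. = FALSE)
  }
  if (!inherits(data$date, "Date")) data$date <- as.Date(data$date)
  if (anyNA(data$date)) stop("unparseable dates in profile data", call. = FALSE)
  if (any(data$depth_m < 0)) stop("negative depths", call. = FALSE)
  bad <- which(!is.na(data$temp_c) & (data$temp_c < -2 | data$temp_c > 40))
  if (length(bad)) {
    stop(sprintf("temperatures outside -2..40 degC at rows: %s",
                 paste(utils::head(bad, 10), collapse = ", ")), call. = FALSE)
  }
  key <- paste(data$date, data$depth_m)
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    stop(sprintf("duplicate (date, depth) observations at rows: %s",
                 paste(utils::head(dup, 10), collapse = ", ")), call. = FALSE)
  }
  depths <- sort(unique(data$depth_m))
  if (!(3 %in% depths) || !any(depths >= 10)) {
    warning("profile series incomplete: needs the 3 m horizon and a depth >= 10 m",
            call. = FALSE)
  }
  if (!is.null(ice_off)) {
    stopifnot(all(c("year", "ice_off_date") %in% names(ice_off)))
    ice_off$ice_off_date <- as.Date(ice_off$ice_off_date)
  }
  data <- data[order(data$date, data$depth_m), , drop = FALSE]
  rownames(data) <- NULL
  attr(data, "site_id") <- site_id
  attr(data, "ice_off") <- ice_off
  class(data) <- c("profile_series", "data.frame")
  data
}

#' Interpolate observed profiles to daily resolution
#'
#' Linear interpolation in time, separately per depth and year. Observation
#' days are reproduced exactly; spans between observations longer than
#' \code{max_gap_days} are left missing.
#'
#' @param profiles a \code{profile_series}.
#' @param max_gap_days longest observation gap (days) bridged by
#'   interpolation; default 21.
#' @return a data frame of class \code{daily_series} with columns
#'   \code{year}, \code{day_of_year}, \code{depth_m}, \code{temp_c},
#'   \code{interpolated}.
#' @export
interpolate_daily <- function(profiles, max_gap_days = 21) {
  stopifnot(inherits(profiles, "profile_series"))
  year <- as.integer(format(profiles$date, "%Y"))
  doy <- doy365(profiles$date)
  out <- list(); k <- 0
  for (y in sort(unique(year))) {
    for (z in sort(unique(profiles$depth_m[year == y]))) {
      sel <- year == y & profiles$depth_m == z & !is.na(profiles$temp_c)
      d <- doy[sel]; v <- profiles$temp_c[sel]
      o <- order(d); d <- d[o]; v <- v[o]
      if (length(d) < 2) {
        warning(sprintf("depth %g m in %d has < 2 observations; left missing",
                        z, y), call. = FALSE)
        next
      }
      days <- seq(d[1], d[length(d)])
      temp <- stats::approx(d, v, xout = days)$y
      # blank out interpolation across gaps longer than max_gap_days
      gap_len <- diff(d)
      for (j in which(gap_len > max_gap_days)) {
        blank <- days > d[j] & days < d[j + 1]
        temp[blank] <- NA_real_
      }
      k <- k + 1
      out[[k]] <- data.frame(
        year = y, day_of_year = days, depth_m = z, temp_c = temp,
        interpolated = !(days %in% d) & !is.na(temp)
      )
    }
  }
  if (!k) stop("no interpolatable depth-years in input", call. = FALSE)
  res <- do.call(rbind, out)
  attr(res, "site_id") <- attr(profiles, "site_id")
  attr(res, "ice_off") <- attr(profiles, "ice_off")
  attr(res, "max_gap_days") <- max_gap_days
  class(res) <- c("daily_series", "data.frame")
  res
}

.daily_at_depth <- function(daily, year, depth) {
  sel <- daily$year == year & daily$depth_m == depth
  v <- rep(NA_real_, 365)
  v[daily$day_of_year[sel]] <- daily$temp_c[sel]
  v
}

#' End of inverse winter stratification (phase 1)
#'
#' Ice-off, when known for the year, takes precedence; otherwise the first
#' day in January-June on which the 3 m temperature exceeds 3 degC.
#'
#' @param daily a \code{daily_series}.
#' @param year calendar year.
#' @param ice_off_day optional day of year of ice-off; overrides the stored
#'   per-year ice-off table.
#' @return day of year, or \code{NA} with a warning if the criterion is never
#'   met by 30 June.
#' @export
detect_phase1_end <- function(daily, year, ice_off_day = NULL) {
  if (is.null(ice_off_day)) {
    tab <- attr(daily, "ice_off")
    if (!is.null(tab) && year %in% tab$year) {
      ice_off_day <- doy365(tab$ice_off_date[match(year, tab$year)])
    }
  }
  if (!is.null(ice_off_day) && !is.na(ice_off_day)) return(as.integer(ice_off_day))
  t3 <- .daily_at_depth(daily, year, 3)[1:SPRING_LAST_DAY]
  hit <- which(!is.na(t3) & t3 > PHASE1_TEMP_C)
  if (!length(hit)) {
    warning(sprintf("phase 1 end not detected in %d", year), call. = FALSE)
    return(NA_integer_)
  }
  hit[1]
}

#' Start of spring overturn (phase 2)
#'
#' First day in January-June on which the whole water column from the
#' surface down to \code{deep_ref_depth} has warmed to at least 4 degC
#' (spring crossing of 4 degC homothermy). In a dimictic winter the deep
#' water sits near 4 degC under a colder surface, so the upward crossing of
#' the column minimum through 4 degC marks the overturn onset.
#'
#' @inheritParams detect_phase1_end
#' @param deep_ref_depth deepest depth (m) required to reach 4 degC;
#'   10 or 15 m depending on site morphometry. Default 10.
#' @return day of year or \code{NA} with a warning.
#' @export
detect_phase2_start <- function(daily, year, deep_ref_depth = 10) {
  depths <- sort(unique(daily$depth_m[daily$year == year]))
  depths <- depths[depths <= deep_ref_depth]
  if (!length(depths) || max(depths) < deep_ref_depth) {
    warning(sprintf("no depth coverage to %g m in %d", deep_ref_depth, year),
            call. = FALSE)
    return(NA_integer_)
  }
  mat <- vapply(depths, function(z) .daily_at_depth(daily, year, z),
                numeric(365))[1:SPRING_LAST_DAY, , drop = FALSE]
  col_min <- apply(mat, 1, function(r) if (anyNA(r)) NA_real_ else min(r))
  hit <- which(!is.na(col_min) & col_min >= PHASE2_TEMP_C)
  if (!length(hit)) {
    warning(sprintf("phase 2 start not detected in %d", year), call. = FALSE)
    return(NA_integer_)
  }
  hit[1]
}

#' Start of early thermal stratification (phase 3)
#'
#' First day (after spring overturn, when its start is known) on which the
#' 3 m temperature exceeds 10 degC. First-crossing convention: later dips
#' below 10 degC do not move the start.
#'
#' @inheritParams detect_phase1_end
#' @param after_day search from this day of year (exclusive); typically the
#'   detected phase-2 start. \code{NULL} searches from 1 January.
#' @param last_day last day of year searched; default 212 (end of July).
#' @return day of year or \code{NA} with a warning.
#' @export
detect_phase3_start <- function(daily, year, after_day = NULL, last_day = 212) {
  t3 <- .daily_at_depth(daily, year, 3)[1:last_day]
  from <- if (is.null(after_day) || is.na(after_day)) 1L else as.integer(after_day)
  hit <- which(!is.na(t3) & t3 > PHASE3_TEMP_C)
  hit <- hit[hit >= from]
  if (!length(hit)) {
    warning(sprintf("phase 3 start not detected in %d", year), call. = FALSE)
    return(NA_integer_)
  }
  hit[1]
}

#' Latitude-shifted calendar windows of the four phases
#'
#' Reference-latitude windows (shift 0): phase 1 from 1 January to 15 March
#' (day 74); phase 2 evaluated on 1 April (day 91); phase 3 the 31 days from
#' 1 May (days 121-151); phase 4 the 31 days from 1 July (days 182-212).
#' The latitudinal shift moves the start of phases 2-4 and the end of phase
#' 1; the phase-1 window always begins on 1 January. The shift is rounded
#' half-up to whole days.
#'
#' @param shift_days signed latitudinal shift in days (|shift| <= 40).
#' @return a data frame with columns \code{phase}, \code{start_day},
#'   \code{end_day} (\code{start_day == end_day} for the single-day phase 2).
#' @export
phase_windows <- function(shift_days = 0) {
  if (!is.finite(shift_days) || abs(shift_days) > 40) {
    stop("|shift_days| must be <= 40", call. = FALSE)
  }
  r <- as.integer(floor(shift_days + 0.5))  # half-up
  data.frame(
    phase = 1:4,
    start_day = c(1L, 91L + r, 121L + r, 182L + r),
    end_day = c(74L + r, 91L + r, 151L + r, 212L + r)
  )
}

#' Time-weighted phase-mean temperatures for one year
#'
#' Phases 1, 3 and 4: arithmetic mean of the daily 3 m temperature over the
#' (shifted) window -- at daily resolution the time weighting is uniform.
#' Phase 2: the temperature at \code{deep_ref_depth} on the single (shifted)
#' evaluation day, with a nearest-available fallback within
#' \code{phase2_fallback_days} days, flagged when used.
#'
#' @inheritParams detect_phase1_end
#' @param shift_days signed latitudinal shift in days.
#' @param deep_ref_depth depth (m) read for phase 2; default 10.
#' @param min_coverage minimum fraction of non-missing days required inside a
#'   window (default 0.8); below it the phase mean is left missing.
#' @param phase2_fallback_days how far (days) to look for a substitute when
#'   the phase-2 evaluation day is missing; default 3.
#' @return a one-row data frame: \code{year}, \code{phase1}..\code{phase4}
#'   mean temperatures, window bounds and a \code{phase2_substituted} flag.
#' @export
phase_mean_temperatures <- function(daily, year, shift_days = 0,
                                    deep_ref_depth = 10, min_coverage = 0.8,
                                    phase2_fallback_days = 3) {
  win <- phase_windows(shift_days)
  t3 <- .daily_at_depth(daily, year, 3)
  t_deep <- .daily_at_depth(daily, year, deep_ref_depth)
  window_mean <- function(w) {
    v <- t3[win$start_day[w]:win$end_day[w]]
    if (mean(!is.na(v)) < min_coverage) {
      warning(sprintf("phase %d coverage below %.0f%% in %d", w,
                      100 * min_coverage, year), call. = FALSE)
      return(NA_real_)
    }
    mean(v, na.rm = TRUE)
  }
  p2_day <- win$start_day[2]
  p2 <- t_deep[p2_day]
  substituted <- FALSE
  if (is.na(p2) && phase2_fallback_days > 0) {
    cand <- p2_day + setdiff(
      seq(-phase2_fallback_days, phase2_fallback_days)[
        order(abs(seq(-phase2_fallback_days, phase2_fallback_days)))], 0)
    cand <- cand[cand >= 1 & cand <= 365]
    ok <- cand[!is.na(t_deep[cand])]
    if (length(ok)) {
      p2 <- t_deep[ok[1]]
      substituted <- TRUE
      warning(sprintf(
        "phase 2 value in %d substituted from day %d (evaluation day %d missing)",
        year, ok[1], p2_day), call. = FALSE)
    } else {
      warning(sprintf("phase 2 value missing in %d", year), call. = FALSE)
    }
  }
  data.frame(
    year = year,
    phase1 = window_mean(1), phase2 = p2,
    phase3 = window_mean(3), phase4 = window_mean(4),
    p1_start = win$start_day[1], p1_end = win$end_day[1],
    p2_day = p2_day,
    p3_start = win$start_day[3], p3_end = win$end_day[3],
    p4_start = win$start_day[4], p4_end = win$end_day[4],
    phase2_substituted = substituted
  )
}

#' Phase timings and means for every year of a series
#'
#' Convenience wrapper running detection and window means over all years of
#' an interpolated series.
#'
#' @param daily a \code{daily_series}.
#' @param shift_days signed latitudinal shift applied to the windows.
#' @param deep_ref_depth depth (m) used for phase-2 homothermy and means.
#' @param ... passed to \code{\link{phase_mean_temperatures}}.
#' @return a data frame, one row per year: detected timings
#'   (\code{phase1_end_day}, \code{phase2_start_day}, \code{phase3_start_day},
#'   \code{phase4_start_day}) and the phase means.
#' @export
phase_table <- function(daily, shift_days = 0, deep_ref_depth = 10, ...) {
  years <- sort(unique(daily$year))
  rows <- lapply(years, function(y) {
    p1 <- suppressWarnings(detect_phase1_end(daily, y))
    p2 <- suppressWarnings(detect_phase2_start(daily, y, deep_ref_depth))
    p3 <- suppressWarnings(detect_phase3_start(daily, y, after_day = p2))
    means <- suppressWarnings(
      phase_mean_temperatures(daily, y, shift_days, deep_ref_depth, ...)
    )
    r <- as.integer(floor(shift_days + 0.5))
    cbind(
      data.frame(year = y, phase1_end_day = p1, phase2_start_day = p2,
                 phase3_start_day = p3, phase4_start_day = 182L + r),
      means[-1]
    )
  })
  do.call(rbind, rows)
}
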