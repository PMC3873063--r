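# File formats and the full-pipeline orchestrator.
#
# CSV dialect: comma-separated, UTF-8, ISO-8601 dates, '.' decimal
# separator, empty fields for missing values.

#' Read a long-format profile CSV
#'
#' Expected header: \code{date,depth_m,temp_c}. Malformed rows (unparseable
#' dates, duplicated (date, depth) pairs, out-of-range temperatures) raise
#' validation errors naming the offending lines.
#'
#' @param path CSV file path.
#' @param site_id site identifier attached to the series.
#' @param ice_off_path optional CSV \code{year,ice_off_date}.
#' @return a \code{\link{profile_series}}.
#' @export
read_profile_csv <- function(path, site_id = basename(path),
                             ice_off_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "depth_m", "temp_c")
  if (!identical(names(df)[seq_along(need)], need)) {
    stop(sprintf("%s: expected columns date,depth_m,temp_c; found %s",
                 path, paste(names(df), collapse = ",")), call. = FALSE)
  }
  dates <- as.Date(df$date, format = "%Y-%m-%d")
  bad <- which(is.na(dates) & !is.na(df$date) & nzchar(df$date))
  if (length(bad)) {
    stop(sprintf("%s: non-ISO dates at line(s) %s", path,
                 paste(utils::head(bad + 1, 10), collapse = ", ")),
         call. = FALSE)
  }
  df$date <- dates
  key <- paste(df$date, df$depth_m)
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    stop(sprintf("%s: duplicated (date, depth) at line(s) %s", path,
                 paste(utils::head(dup + 1, 10), collapse = ", ")),
         call. = FALSE)
  }
  ice <- if (!is.null(ice_off_path)) {
    utils::read.csv(ice_off_path, stringsAsFactors = FALSE)
  }
  profile_series(df, site_id = site_id, ice_off = ice)
}

#' Write a profile series to CSV
#'
#' @param profiles a \code{\link{profile_series}}.
#' @param path output path.
#' @export
write_profile_csv <- function(profiles, path) {
  df <- as.data.frame(profiles)[c("date", "depth_m", "temp_c")]
  df$date <- format(df$date, "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write / read a CW grid
#'
#' Grid file format: \code{year,phase1,phase2,phase3,phase4} with values
#' C, W or empty (missing). Write-then-read reproduces the grid exactly.
#'
#' @param grid a \code{\link{cw_grid}}.
#' @param path CSV path.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "cw_grid"))
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_grid
#' @param site_id site identifier attached to the grid on read.
#' @return \code{read_grid} returns a \code{\link{cw_grid}}.
#' @export
read_grid <- function(path, site_id = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("integer", rep("character", 4)),
                        na.strings = c("", "NA"))
  need <- c("year", paste0("phase", 1:4))
  if (!identical(names(df), need)) {
    stop(sprintf("%s: expected columns %s", path, paste(need, collapse = ",")),
         call. = FALSE)
  }
  cw_grid(df$year, as.matrix(df[-1]), site_id = site_id)
}

#' Read a YAML site configuration
#'
#' Fields: \code{site_id}, \code{latitude_deg}, \code{longitude_deg},
#' \code{altitude_m}, \code{system_class} (lake | baltic | north_sea),
#' \code{reference} (logical), optional \code{thresholds} (4 numbers) and
#' \code{deep_ref_depth}.
#'
#' @param path YAML file.
#' @return a list of class \code{site_config}.
#' @export
read_site_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  site_config(cfg)
}

#' Validate a site configuration list
#'
#' @param cfg named list of site fields (see \code{\link{read_site_config}}).
#' @return the list, completed with defaults, of class \code{site_config}.
#' @export
site_config <- function(cfg) {
  if (is.null(cfg$site_id)) stop("site_id missing", call. = FALSE)
  if (is.null(cfg$latitude_deg) || !is.finite(cfg$latitude_deg) ||
      abs(cfg$latitude_deg) > 66) {
    stop(sprintf("site %s: latitude_deg missing or outside model validity",
                 cfg$site_id), call. = FALSE)
  }
  cfg$system_class <- match.arg(cfg$system_class %||% "lake",
                                c("lake", "baltic", "north_sea"))
  cfg$reference <- isTRUE(cfg$reference)
  cfg$deep_ref_depth <- cfg$deep_ref_depth %||% 10
  if (!is.null(cfg$thresholds)) {
    cfg$thresholds <- threshold_set(unlist(cfg$thresholds),
                                    system_class = cfg$system_class)
  }
  class(cfg) <- "site_config"
  cfg
}

#' Run the full CW-coding pipeline over a set of sites
#'
#' For every site: daily interpolation, latitudinal window shift relative to
#' the reference site, phase timings and means, thresholds (site overrides,
#' else estimated from the reference years, else the shipped profile for its
#' system class) and the CW grid. Across sites: the shift table, coherence of
#' every site against the reference grid, logistic warm-probability trends
#' per phase and a Mann-Kendall test on the reference site's yearly warm
#' counts.
#'
#' @param sites named list; each element a list with \code{config} (a
#'   \code{\link{site_config}} or plain list) and \code{profiles} (a
#'   \code{\link{profile_series}}).
#' @param reference_years years used when thresholds are estimated from the
#'   data; default 1990:2009.
#' @param estimate_site_thresholds estimate thresholds from each site's own
#'   means (\code{TRUE}) or use the shipped constant profile for its system
#'   class (default).
#' @param max_gap_days interpolation gap limit, days.
#' @return a list of class \code{cw_pipeline}: per-site results
#'   (\code{sites}), \code{shift_table}, \code{coherence} vs the reference,
#'   \code{trends}, \code{errors} (per-site failure records) and
#'   \code{reference_site}.
#' @export
run_pipeline <- function(sites, reference_years = 1990:2009,
                         estimate_site_thresholds = FALSE,
                         max_gap_days = 21) {
  configs <- lapply(sites, function(s) {
    if (inherits(s$config, "site_config")) s$config else site_config(s$config)
  })
  is_ref <- vapply(configs, function(c) c$reference, logical(1))
  if (sum(is_ref) != 1) {
    stop("exactly one site must be flagged as the reference", call. = FALSE)
  }
  ref_name <- names(sites)[is_ref]
  ref_lat <- configs[[ref_name]]$latitude_deg

  results <- list(); errors <- list()
  for (nm in names(sites)) {
    res <- tryCatch({
      cfg <- configs[[nm]]
      shift <- if (nm == ref_name) 0 else
        latitudinal_shift_days(ref_lat, cfg$latitude_deg)$mean_shift_days
      daily <- interpolate_daily(sites[[nm]]$profiles, max_gap_days)
      tab <- suppressWarnings(
        phase_table(daily, shift_days = shift,
                    deep_ref_depth = cfg$deep_ref_depth)
      )
      thr <- if (!is.null(cfg$thresholds)) cfg$thresholds
        else if (estimate_site_thresholds)
          estimate_thresholds(tab, reference_years,
                              rounding = if (cfg$system_class == "lake")
                                "integer" else "none")
        else threshold_profile(cfg$system_class)
      grid <- classify_grid(tab, thr, site_id = cfg$site_id)
      list(config = cfg, shift_days = shift, phase_table = tab,
           thresholds = thr, grid = grid)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[nm]] <- conditionMessage(res)
    } else {
      results[[nm]] <- res
    }
  }
  if (is.null(results[[ref_name]])) {
    stop(sprintf("reference site failed: %s", errors[[ref_name]]),
         call. = FALSE)
  }
  ref_grid <- results[[ref_name]]$grid

  shift_table <- data.frame(
    site = names(results),
    latitude_deg = vapply(results, function(r) r$config$latitude_deg, numeric(1)),
    shift_days = vapply(results, function(r) r$shift_days, numeric(1)),
    row.names = NULL
  )
  coherence <- lapply(results[setdiff(names(results), ref_name)],
                      function(r) coherence_summary(ref_grid, r$grid))

  warm_counts <- count_warm_per_year(ref_grid)
  trends <- list(
    per_phase = lapply(1:4, function(p) {
      codes <- ref_grid[[paste0("phase", p)]]
      tryCatch(fit_logistic_trend(ref_grid$year, codes),
               error = function(e) conditionMessage(e))
    }),
    mann_kendall_warm_counts = tryCatch(
      mann_kendall(as.numeric(warm_counts)),
      error = function(e) conditionMessage(e))
  )

  structure(list(
    sites = results, shift_table = shift_table, coherence = coherence,
    trends = trends, errors = errors, reference_site = ref_name
  ), class = "cw_pipeline")
}

#' Export a radiation curve as CSV
#'
#' @param curve a \code{\link{radiation_curve}}.
#' @param path output CSV path.
#' @export
write_radiation_csv <- function(curve, path) {
  stopifnot(inherits(curve, "radiation_curve"))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
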