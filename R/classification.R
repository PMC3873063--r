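# Cold/warm coding: threshold estimation over a reference period and
# classification of every phase-year into the dual CW code.

#' Shipped threshold profiles
#'
#' Per-phase temperature thresholds separating warm (mean >= threshold) from
#' cold phases. The lake profile (3, 4, 14, 20 degC) is the constant profile
#' used for the first cross-system coherence comparison; the Baltic and
#' North Sea profiles are station averages kept at one decimal.
#'
#' @param system_class one of \code{"lake"}, \code{"baltic"},
#'   \code{"north_sea"}.
#' @return a named numeric vector of class \code{threshold_set} with elements
#'   \code{phase1}..\code{phase4}.
#' @export
threshold_profile <- function(system_class = c("lake", "baltic", "north_sea")) {
  system_class <- match.arg(system_class)
  v <- switch(system_class,
    lake = c(3, 4, 14, 20),
    baltic = c(3.0, 4.0, 11.5, 18.3),
    north_sea = c(5.5, 5.8, 10.8, 17.0)
  )
  threshold_set(v, system_class = system_class)
}

#' Construct a threshold set
#'
#' @param values numeric vector of four per-phase thresholds (degC).
#' @param system_class label: lake, baltic, north_sea or custom.
#' @param rounding \code{"integer"} or \code{"none"} (metadata describing how
#'   the values were derived).
#' @return a named numeric vector of class \code{threshold_set}.
#' @export
threshold_set <- function(values, system_class = "custom", rounding = "none") {
  stopifnot(length(values) == 4, all(is.finite(values) | is.na(values)))
  v <- as.numeric(values)
  names(v) <- paste0("phase", 1:4)
  if (!anyNA(v[2:4]) && !all(diff(v[2:4]) > 0)) {
    warning("thresholds for phases 2..4 are not strictly increasing",
            call. = FALSE)
  }
  attr(v, "system_class") <- system_class
  attr(v, "rounding") <- rounding
  class(v) <- "threshold_set"
  v
}

# round half away from zero (positive thresholds: half-up)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Estimate cold/warm thresholds from a reference period
#'
#' Per-phase arithmetic mean of the yearly phase-mean temperatures over the
#' reference years, rounded half-up to the integer for lakes or kept
#' unrounded for marine stations.
#'
#' @param phase_means a data frame with columns \code{year} and
#'   \code{phase1}..\code{phase4} (as returned by \code{\link{phase_table}}).
#' @param reference_years integer vector of years entering the averages
#'   (e.g. \code{1990:2009}).
#' @param rounding \code{"integer"} (lakes) or \code{"none"} (marine).
#' @param min_years minimum number of non-missing years per phase; default 5.
#' @return a \code{\link{threshold_set}}.
#' @export
estimate_thresholds <- function(phase_means, reference_years,
                                rounding = c("integer", "none"),
                                min_years = 5) {
  rounding <- match.arg(rounding)
  sel <- phase_means$year %in% reference_years
  v <- vapply(paste0("phase", 1:4), function(p) {
    x <- phase_means[[p]][sel]
    x <- x[!is.na(x)]
    if (length(x) < min_years) return(NA_real_)
    mean(x)
  }, numeric(1))
  if (anyNA(v)) {
    stop(sprintf(
      "fewer than %d reference years with data for phase(s): %s",
      min_years, paste(which(is.na(v)), collapse = ", ")), call. = FALSE)
  }
  if (rounding == "integer") v <- round_half_up(v)
  threshold_set(v, system_class = "custom", rounding = rounding)
}

#' Classify the four phases of one year as cold or warm
#'
#' A phase is warm (\code{"W"}) when its mean temperature equals or exceeds
#' the threshold, cold (\code{"C"}) when it falls below, and \code{NA} when
#' the mean is missing.
#'
#' @param means numeric vector of four phase-mean temperatures (degC).
#' @param thresholds a \code{\link{threshold_set}}.
#' @return character vector of length 4 with values \code{"C"}, \code{"W"}
#'   or \code{NA}.
#' @export
classify_year <- function(means, thresholds) {
  stopifnot(length(means) == 4, inherits(thresholds, "threshold_set"))
  if (anyNA(unclass(thresholds))) stop("thresholds incomplete", call. = FALSE)
  ifelse(is.na(means), NA_character_,
         ifelse(means >= unclass(thresholds), "W", "C"))
}

#' Assemble a years x phases CW grid
#'
#' @param years integer vector of years (no duplicates).
#' @param codes a length(years) x 4 matrix or data frame of \code{"C"} /
#'   \code{"W"} / \code{NA} codes.
#' @param site_id site identifier.
#' @return a data frame of class \code{cw_grid} with columns \code{year},
#'   \code{phase1}..\code{phase4}.
#' @export
cw_grid <- function(years, codes, site_id = "site") {
  years <- as.integer(years)
  if (anyDuplicated(years)) stop("duplicate years in grid", call. = FALSE)
  codes <- as.matrix(codes)
  stopifnot(nrow(codes) == length(years), ncol(codes) == 4)
  ok <- codes %in% c("C", "W") | is.na(codes)
  if (!all(ok)) stop("codes must be C, W or NA", call. = FALSE)
  g <- data.frame(year = years,
                  phase1 = codes[, 1], phase2 = codes[, 2],
                  phase3 = codes[, 3], phase4 = codes[, 4],
                  stringsAsFactors = FALSE)
  g <- g[order(g$year), , drop = FALSE]
  rownames(g) <- NULL
  attr(g, "site_id") <- site_id
  class(g) <- c("cw_grid", "data.frame")
  g
}

#' Classify every year of a phase-mean table
#'
#' @param phase_means data frame with \code{year} and \code{phase1}..
#'   \code{phase4} mean temperatures.
#' @param thresholds a \code{\link{threshold_set}}.
#' @param site_id site identifier carried on the grid.
#' @return a \code{\link{cw_grid}}.
#' @export
classify_grid <- function(phase_means, thresholds, site_id = "site") {
  codes <- t(apply(phase_means[paste0("phase", 1:4)], 1,
                   classify_year, thresholds = thresholds))
  cw_grid(phase_means$year, codes, site_id = site_id)
}

#' Number of warm phases per year
#'
#' @param grid a \code{\link{cw_grid}}.
#' @return named integer vector (by year) counting \code{"W"} among
#'   non-missing phases, 0..4.
#' @export
count_warm_per_year <- function(grid) {
  stopifnot(inherits(grid, "cw_grid"))
  m <- as.matrix(grid[paste0("phase", 1:4)])
  counts <- apply(m, 1, function(r) sum(r == "W", na.rm = TRUE))
  stats::setNames(as.integer(counts), grid$year)
}

#' @export
print.cw_grid <- function(x, ...) {
  cat(sprintf("CW grid for %s: %d years\n",
              attr(x, "site_id") %||% "site", nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
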