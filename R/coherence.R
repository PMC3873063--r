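# Cross-system coherence of CW codes: 2x2 contingency tables of matching and
# non-matching classifications against a reference system, with similarity
# percentage, Phi coefficient, odds ratio and Fisher's exact test.

#' Construct a 2x2 contingency table of CW matches
#'
#' @param ncc years/phases cold in both systems.
#' @param nww warm in both.
#' @param ncw reference cold, site warm.
#' @param nwc reference warm, site cold.
#' @return an object of class \code{contingency_2x2}.
#' @export
contingency_2x2 <- function(ncc, nww, ncw, nwc) {
  counts <- c(ncc = ncc, nww = nww, ncw = ncw, nwc = nwc)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) == 0) stop("empty contingency table", call. = FALSE)
  structure(as.list(counts), class = "contingency_2x2")
}

as_matrix_2x2 <- function(tab) {
  # rows: reference C/W; columns: site C/W
  matrix(c(tab$ncc, tab$nwc, tab$ncw, tab$nww), nrow = 2,
         dimnames = list(reference = c("C", "W"), site = c("C", "W")))
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  print(as_matrix_2x2(x))
  invisible(x)
}

#' Build the match/mismatch contingency table of two CW grids
#'
#' Pools the selected phases over the overlapping years of the two grids.
#' Phase-slots missing in either grid are skipped, never imputed.
#'
#' @param grid_ref reference-system \code{\link{cw_grid}} (the "prediction").
#' @param grid_site compared-system \code{\link{cw_grid}} (the "observation").
#' @param phases subset of 1..4 to pool; default all four.
#' @return a \code{\link{contingency_2x2}}.
#' @export
build_contingency <- function(grid_ref, grid_site, phases = 1:4) {
  stopifnot(inherits(grid_ref, "cw_grid"), inherits(grid_site, "cw_grid"),
            all(phases %in% 1:4))
  years <- intersect(grid_ref$year, grid_site$year)
  if (!length(years)) stop("no overlapping years", call. = FALSE)
  cols <- paste0("phase", phases)
  a <- as.matrix(grid_ref[match(years, grid_ref$year), cols, drop = FALSE])
  b <- as.matrix(grid_site[match(years, grid_site$year), cols, drop = FALSE])
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("no usable (year, phase) pairs", call. = FALSE)
  contingency_2x2(
    ncc = sum(a == "C" & b == "C" & ok, na.rm = TRUE),
    nww = sum(a == "W" & b == "W" & ok, na.rm = TRUE),
    ncw = sum(a == "C" & b == "W" & ok, na.rm = TRUE),
    nwc = sum(a == "W" & b == "C" & ok, na.rm = TRUE)
  )
}

#' Similarity percentage of two CW code series
#'
#' Share of (year, phase) slots with matching classification, in percent:
#' 100 (Ncc + Nww) / N.
#'
#' @param tab a \code{\link{contingency_2x2}}.
#' @return percentage in 0..100.
#' @export
similarity_percent <- function(tab) {
  stopifnot(inherits(tab, "contingency_2x2"))
  n <- tab$ncc + tab$nww + tab$ncw + tab$nwc
  100 * (tab$ncc + tab$nww) / n
}

#' Phi coefficient of a 2x2 table
#'
#' The mean-square contingency coefficient, equal to the Pearson correlation
#' of the two binary classifications. Undefined (returned as \code{NA} with a
#' warning) when any margin is zero.
#'
#' @param tab a \code{\link{contingency_2x2}}.
#' @return value in [-1, 1], or \code{NA} when a margin is empty.
#' @export
phi_coefficient <- function(tab) {
  stopifnot(inherits(tab, "contingency_2x2"))
  m <- c(tab$ncc + tab$ncw, tab$nwc + tab$nww,  # reference margins
         tab$ncc + tab$nwc, tab$ncw + tab$nww)  # site margins
  if (any(m == 0)) {
    warning("phi undefined: a margin of the 2x2 table is zero", call. = FALSE)
    return(NA_real_)
  }
  (tab$ncc * tab$nww - tab$ncw * tab$nwc) / sqrt(prod(m))
}

#' Odds ratio of a 2x2 table
#'
#' \code{method = "formula"}: the cross-product ratio
#' (Ncc Nww) / (Ncw Nwc), returning \code{Inf} when only the mismatch product
#' is zero. \code{method = "conditional_mle"}: the conditional
#' maximum-likelihood estimate under the noncentral hypergeometric model
#' (the estimator reported by \code{\link[stats]{fisher.test}}).
#'
#' @param tab a \code{\link{contingency_2x2}}.
#' @param method \code{"formula"} (default) or \code{"conditional_mle"}.
#' @return odds ratio (possibly \code{Inf}); \code{NaN} with a warning for
#'   the degenerate 0/0 formula case.
#' @export
odds_ratio <- function(tab, method = c("formula", "conditional_mle")) {
  stopifnot(inherits(tab, "contingency_2x2"))
  method <- match.arg(method)
  if (method == "formula") {
    num <- tab$ncc * tab$nww
    den <- tab$ncw * tab$nwc
    if (num == 0 && den == 0) {
      warning("odds ratio undefined (0/0)", call. = FALSE)
      return(NaN)
    }
    if (den == 0) return(Inf)
    return(num / den)
  }
  unname(stats::fisher.test(as_matrix_2x2(tab))$estimate)
}

#' Two-sided Fisher's exact test of a 2x2 table
#'
#' Probability-ordering two-sided p: the sum of hypergeometric probabilities
#' of all tables with the observed margins that are no more probable than the
#' observed one.
#'
#' @param tab a \code{\link{contingency_2x2}}.
#' @return two-sided p-value.
#' @export
fisher_exact <- function(tab) {
  stopifnot(inherits(tab, "contingency_2x2"))
  stats::fisher.test(as_matrix_2x2(tab))$p.value
}

#' All coherence statistics of two CW grids
#'
#' Pools the selected phases and reports counts, similarity, Phi, both odds
#' ratios and Fisher's exact p; optionally also per-phase similarities and
#' their mean.
#'
#' @inheritParams build_contingency
#' @param per_phase also compute per-phase similarity percentages.
#' @return a list with the pooled \code{table}, \code{n}, \code{similarity_pct},
#'   \code{phi}, \code{odds_formula}, \code{odds_cmle}, \code{fisher_p}, and
#'   (when \code{per_phase}) \code{similarity_by_phase} and
#'   \code{mean_phase_similarity_pct}.
#' @export
coherence_summary <- function(grid_ref, grid_site, phases = 1:4,
                              per_phase = TRUE) {
  tab <- build_contingency(grid_ref, grid_site, phases)
  out <- list(
    table = tab,
    n = tab$ncc + tab$nww + tab$ncw + tab$nwc,
    similarity_pct = similarity_percent(tab),
    phi = suppressWarnings(phi_coefficient(tab)),
    odds_formula = suppressWarnings(odds_ratio(tab, "formula")),
    odds_cmle = odds_ratio(tab, "conditional_mle"),
    fisher_p = fisher_exact(tab)
  )
  if (per_phase) {
    sims <- vapply(phases, function(p) {
      t1 <- tryCatch(build_contingency(grid_ref, grid_site, p),
                     error = function(e) NULL)
      if (is.null(t1)) NA_real_ else similarity_percent(t1)
    }, numeric(1))
    names(sims) <- paste0("phase", phases)
    out$similarity_by_phase <- sims
    out$mean_phase_similarity_pct <- mean(sims, na.rm = TRUE)
  }
  out
}
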