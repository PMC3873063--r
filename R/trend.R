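# Long-term trend analysis of warm-phase occurrence and phase-conditioned
# response analysis: binomial-logit GLM, Mann-Kendall trend test,
# Brunt-Vaisala stability and cold/warm group comparisons.

#' Logistic trend of warm-phase occurrence
#'
#' Fits P(warm | year) = exp(a + b year) / (1 + exp(a + b year)) by maximum
#' likelihood (binomial GLM, logit link) and reports the deviance reduction
#' against the intercept-only model with its 1-df chi-square p-value.
#' Grids of 30-40 years frequently sit near quasi-separation; the fit is then
#' flagged rather than reported as a converged estimate.
#'
#' @param years integer years.
#' @param outcomes binary warm indicators: 0/1, logical, or \code{"C"}/
#'   \code{"W"} codes; \code{NA} pairs are dropped.
#' @return a list of class \code{logistic_trend}: \code{a}, \code{b},
#'   \code{deviance_reduction}, \code{p_value}, \code{converged},
#'   \code{separation}, \code{n} and the underlying \code{fit}.
#' @export
fit_logistic_trend <- function(years, outcomes) {
  if (is.character(outcomes) || is.factor(outcomes)) {
    outcomes <- c(C = 0, W = 1)[as.character(outcomes)]
  }
  outcomes <- as.numeric(outcomes)
  ok <- !is.na(years) & !is.na(outcomes)
  years <- years[ok]; outcomes <- outcomes[ok]
  if (length(unique(outcomes)) < 2) {
    stop("outcomes contain a single class; no trend is estimable",
         call. = FALSE)
  }
  if (length(years) < 10) {
    warning("fewer than 10 year-outcome pairs; estimates are unstable",
            call. = FALSE)
  }
  warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(outcomes ~ years, family = stats::binomial(),
               control = stats::glm.control(maxit = 50)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        warned <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  co <- stats::coef(fit)
  p_hat <- stats::fitted(fit)
  separation <- warned || !fit$converged ||
    all(p_hat[outcomes == 1] > 1 - 1e-8) && all(p_hat[outcomes == 0] < 1e-8)
  dev_red <- fit$null.deviance - fit$deviance
  structure(list(
    a = unname(co[1]), b = unname(co[2]),
    deviance_reduction = dev_red,
    p_value = stats::pchisq(dev_red, df = 1, lower.tail = FALSE),
    converged = fit$converged && !separation,
    separation = separation,
    n = length(years),
    fit = fit
  ), class = "logistic_trend")
}

#' @export
print.logistic_trend <- function(x, ...) {
  cat(sprintf(
    "logistic trend: a = %.4g, b = %.5g, dev = %.3g, p = %.4g%s (n = %d)\n",
    x$a, x$b, x$deviance_reduction, x$p_value,
    if (x$separation) " [quasi-separation]" else "", x$n))
  invisible(x)
}

#' Warm-phase probability from logistic trend coefficients
#'
#' Evaluates y = exp(a + b x) / (1 + exp(a + b x)).
#'
#' @param a intercept on the logit scale.
#' @param b slope per year.
#' @param year year(s) at which to evaluate.
#' @return probability in (0, 1).
#' @examples
#' predict_warm_probability(-304.15, 0.15148, 2010)
#' @export
predict_warm_probability <- function(a, b, year) {
  stopifnot(is.finite(a), is.finite(b))
  stats::plogis(a + b * year)
}

#' Mann-Kendall trend test
#'
#' Kendall's S statistic from pairwise sign concordance against time order,
#' tau-b with tie correction, and a two-sided p-value from the normal
#' approximation with continuity correction.
#'
#' @param x numeric series in time order (yearly values).
#' @return a list: \code{tau}, \code{p_value}, \code{S}, \code{var_S},
#'   \code{n}.
#' @export
mann_kendall <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 4) stop("need at least 4 non-missing values", call. = FALSE)
  if (length(unique(x)) == 1) {
    stop("all values equal; tau is undefined", call. = FALSE)
  }
  s <- 0
  for (i in seq_len(n - 1)) {
    s <- s + sum(sign(x[(i + 1):n] - x[i]))
  }
  ties <- table(x)
  ties <- ties[ties > 1]
  n0 <- n * (n - 1) / 2
  tie_term <- sum(ties * (ties - 1) / 2)
  tau <- s / sqrt((n0 - tie_term) * n0)  # tau-b; time has no ties
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  z <- if (s > 0) (s - 1) / sqrt(var_s) else if (s < 0) (s + 1) / sqrt(var_s) else 0
  list(tau = tau, p_value = 2 * stats::pnorm(-abs(z)), S = s, var_S = var_s,
       n = n)
}

#' Density of pure water at atmospheric pressure
#'
#' Kell (1975) polynomial; maximum near 3.98 degC. Salinity is taken as zero
#' throughout: stability in the package is about relative freshwater density
#' gradients.
#'
#' @param temp_c temperature(s) in degC.
#' @return density in kg m^-3.
#' @export
water_density <- function(temp_c) {
  t <- temp_c
  (999.83952 + 16.945176 * t - 7.9870401e-3 * t^2 - 46.170461e-6 * t^3 +
     105.56302e-9 * t^4 - 280.54253e-12 * t^5) / (1 + 16.87985e-3 * t)
}

#' Brunt-Vaisala stability of a temperature profile
#'
#' Buoyancy frequency squared N^2 = (g / rho) d(rho)/dz with z positive
#' downward, from centered finite differences of freshwater density over the
#' requested depth range (one-sided at the range ends). Unstable layers
#' (negative N^2) are clipped to zero and flagged. The mean stability
#' frequency is the mean of sqrt(N^2) over the range, in s^-1.
#'
#' @param depths depths in m (positive downward).
#' @param temps matching temperatures in degC.
#' @param depth_range numeric length-2 interval of depths (m) to evaluate;
#'   default c(0, 15).
#' @return a list of class \code{stability_profile}: \code{depths},
#'   \code{n_squared} (s^-2), \code{mean_frequency} (s^-1), \code{clipped}.
#' @export
brunt_vaisala <- function(depths, temps, depth_range = c(0, 15)) {
  stopifnot(length(depths) == length(temps), length(depth_range) == 2)
  ok <- !is.na(depths) & !is.na(temps)
  depths <- depths[ok]; temps <- temps[ok]
  if (anyDuplicated(depths)) stop("duplicate depths", call. = FALSE)
  if (is.unsorted(depths)) {
    warning("depths not in increasing order; sorting", call. = FALSE)
    o <- order(depths); depths <- depths[o]; temps <- temps[o]
  }
  sel <- depths >= depth_range[1] & depths <= depth_range[2]
  z <- depths[sel]; tt <- temps[sel]
  if (length(z) < 3) {
    stop("need at least 3 depths inside the range", call. = FALSE)
  }
  g <- 9.81
  rho <- water_density(tt)
  k <- length(z)
  drho_dz <- numeric(k)
  drho_dz[1] <- (rho[2] - rho[1]) / (z[2] - z[1])
  drho_dz[k] <- (rho[k] - rho[k - 1]) / (z[k] - z[k - 1])
  if (k > 2) {
    i <- 2:(k - 1)
    drho_dz[i] <- (rho[i + 1] - rho[i - 1]) / (z[i + 1] - z[i - 1])
  }
  n2 <- g / rho * drho_dz
  clipped <- any(n2 < 0)
  n2 <- pmax(n2, 0)
  structure(list(
    depths = z,
    n_squared = n2,
    mean_frequency = mean(sqrt(n2)),
    clipped = clipped
  ), class = "stability_profile")
}

#' Response variable split by the cold/warm code of one phase
#'
#' Splits a yearly response series into the years classified cold vs warm
#' for the given phase, then compares the two groups: Levene's test on
#' absolute deviations from group medians (variance homogeneity) and a
#' two-sided Mann-Whitney U test (exact for small tie-free samples, normal
#' approximation with tie correction otherwise), plus five-number summaries
#' (the box-plot surface).
#'
#' @param response data frame with columns \code{year} and \code{value}.
#' @param grid a \code{\link{cw_grid}}.
#' @param phase phase number 1..4.
#' @param min_group_n smallest per-group size for which the tests are
#'   computed; default 3. Below it, summaries are still returned.
#' @return a list: \code{group_C}, \code{group_W} (values),
#'   \code{levene_p}, \code{u_statistic}, \code{u_p}, \code{summary_C},
#'   \code{summary_W} (5/25/50/75/95th percentiles), \code{tested}.
#' @export
response_by_code <- function(response, grid, phase, min_group_n = 3) {
  stopifnot(inherits(grid, "cw_grid"), phase %in% 1:4,
            all(c("year", "value") %in% names(response)))
  code <- grid[[paste0("phase", phase)]][match(response$year, grid$year)]
  ok <- !is.na(code) & !is.na(response$value)
  vals <- response$value[ok]; code <- code[ok]
  gc <- vals[code == "C"]; gw <- vals[code == "W"]
  qs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  fivenum_q <- function(v) {
    if (!length(v)) return(stats::setNames(rep(NA_real_, 5), paste0("q", qs * 100)))
    stats::setNames(stats::quantile(v, qs, names = FALSE), paste0("q", qs * 100))
  }
  out <- list(group_C = gc, group_W = gw,
              summary_C = fivenum_q(gc), summary_W = fivenum_q(gw),
              levene_p = NA_real_, u_statistic = NA_real_, u_p = NA_real_,
              tested = FALSE)
  if (length(gc) < min_group_n || length(gw) < min_group_n) {
    warning(sprintf("a group has fewer than %d years; tests suppressed",
                    min_group_n), call. = FALSE)
    return(out)
  }
  grp <- factor(code, levels = c("C", "W"))
  lev <- car::leveneTest(vals ~ grp, center = stats::median)
  out$levene_p <- lev[["Pr(>F)"]][1]
  wt <- suppressWarnings(
    stats::wilcox.test(gc, gw, alternative = "two.sided",
                       exact = length(gc) <= 20 && length(gw) <= 20,
                       correct = TRUE)
  )
  out$u_statistic <- unname(wt$statistic)
  out$u_p <- wt$p.value
  out$tested <- TRUE
  out
}
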