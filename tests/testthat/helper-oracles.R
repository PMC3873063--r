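# Independent oracles and fixture builders used across the suite.
# Oracles are deliberately naive (loops, enumeration) and share no code with
# the implementation paths they check.

# daily radiation by 1-minute stepping through the same transmission model,
# written out directly (independent of the package's vectorised quadrature)
oracle_daily_radiation <- function(lat_deg, doy, turbidity = 2) {
  phi <- lat_deg * pi / 180
  g <- 2 * pi * (doy - 1) / 365
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.001480 * sin(3 * g)
  e0 <- 1 + 0.033 * cos(2 * pi * doy / 365)
  total <- 0
  for (minute in seq(0.5, 24 * 60 - 0.5, by = 1)) {
    omega <- (minute / (24 * 60)) * 2 * pi - pi
    sinh_ <- sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(omega)
    if (sinh_ <= 0) next
    h <- asin(sinh_)
    hd <- h * 180 / pi
    m <- 1 / (sinh_ + 0.50572 * (hd + 6.07995)^-1.6364)
    dR <- if (m <= 20) {
      1 / (6.6296 + 1.7513 * m - 0.1202 * m^2 + 0.0065 * m^3 - 0.00013 * m^4)
    } else 1 / (10.4 + 0.718 * m)
    tb <- exp(-0.8662 * turbidity * m * dR)
    ext <- 1367 * e0 * sinh_
    total <- total + (ext * tb + ext * max(0.2710 - 0.2939 * tb, 0)) * 60
  }
  total * 1e-7
}

# two-sided Fisher p by full enumeration of margin-consistent tables
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(xs, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# conditional-MLE odds ratio by grid search over the noncentral
# hypergeometric conditional likelihood
oracle_cmle_odds <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  xs <- max(0, c1 - r2):min(r1, c1)
  log_binom <- lchoose(r1, xs) + lchoose(r2, c1 - xs)
  loglik <- function(log_psi) {
    terms <- log_binom + xs * log_psi
    (log_binom[xs == a] + a * log_psi) - max(terms) -
      log(sum(exp(terms - max(terms))))
  }
  grid <- seq(-8, 8, by = 1e-4)
  exp(grid[which.max(vapply(grid, loglik, numeric(1)))])
}

# Kendall S and tau-b by explicit pair loops
oracle_kendall_tau <- function(x) {
  n <- length(x)
  s <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) s <- s + sign(x[j] - x[i])
  ties <- table(x); ties <- ties[ties > 1]
  n0 <- n * (n - 1) / 2
  list(S = s, tau = s / sqrt((n0 - sum(ties * (ties - 1) / 2)) * n0))
}

# Mann-Whitney U of sample x vs y by explicit pair counting
oracle_u_statistic <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  }
  u
}

# N^2 recomputed directly from density values by finite differences
oracle_n_squared <- function(z, rho) {
  k <- length(z)
  d <- numeric(k)
  d[1] <- (rho[2] - rho[1]) / (z[2] - z[1])
  d[k] <- (rho[k] - rho[k - 1]) / (z[k] - z[k - 1])
  if (k > 2) for (i in 2:(k - 1)) {
    d[i] <- (rho[i + 1] - rho[i - 1]) / (z[i + 1] - z[i - 1])
  }
  pmax(9.81 / rho * d, 0)
}

# daily series fixture built directly from per-depth daily vectors
make_daily_series <- function(year, depth_temps) {
  rows <- lapply(names(depth_temps), function(z) {
    v <- depth_temps[[z]]
    data.frame(year = year, day_of_year = seq_along(v),
               depth_m = as.numeric(z), temp_c = v, interpolated = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("daily_series", "data.frame")
  out
}

# the standard noisy classification-recovery scenario: alternating +-1.5 degC
# year offsets, 0.3 degC observation noise, weekly sampling
standard_recovery_scenario <- function(years = 36, seed = 42) {
  lake_scenario(
    years = years,
    year_offsets_c = rep(c(1.5, -1.5), length.out = years),
    observation_noise_sd_c = 0.3,
    sampling_interval_days = 7,
    seed = seed
  )
}
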