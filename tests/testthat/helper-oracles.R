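# Independent oracles used across the suite. Each is a deliberately naive,
# literal implementation kept separate from the package's code paths.

# USGS DOTABLES freshwater oxygen solubility at 760 mmHg, integer degC 0..40
USGS_O2_TABLE <- c(
  14.62, 14.22, 13.83, 13.46, 13.11, 12.77, 12.45, 12.14, 11.84, 11.56,
  11.29, 11.03, 10.78, 10.54, 10.31, 10.08, 9.87, 9.66, 9.47, 9.28,
  9.09, 8.91, 8.74, 8.58, 8.42, 8.26, 8.11, 7.97, 7.83, 7.69,
  7.56, 7.43, 7.30, 7.18, 7.07, 6.95, 6.84, 6.73, 6.62, 6.52, 6.41
)

# literal step-by-step transcription of the chromaticity hue-angle equations
oracle_hue <- function(r_blue, r_green, r_red) {
  X <- 2.7689 * r_red + 1.7517 * r_green + 1.1302 * r_blue
  Y <- 1.0000 * r_red + 4.5906 * r_green + 0.0601 * r_blue
  Z <- 0.0565 * r_green + 5.5943 * r_blue
  x <- X / (X + Y + Z)
  y <- Y / (X + Y + Z)
  a <- atan2(x - 0.33, y - 0.33) * 180 / pi + 180
  da <- -1.8185 * (a / 100)^5 - 62.461 * (a / 100)^4 + 320.49 * (a / 100)^3 -
    510.97 * (a / 100)^2 + 306.32 * (a / 100) - 50.343
  list(a = a, delta_a = da, a_prime = a - da)
}

# brute-force Theil-Sen: explicit double loop over all pairs
oracle_theil_sen <- function(t, y) {
  slopes <- c()
  n <- length(t)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (t[j] != t[i]) slopes <- c(slopes, (y[j] - y[i]) / (t[j] - t[i]))
  }
  median(slopes)
}

# brute-force Mann-Kendall S and tie-corrected variance
oracle_mk <- function(y) {
  n <- length(y)
  s <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) s <- s + sign(y[j] - y[i])
  tie_term <- 0
  for (v in unique(y)) {
    tq <- sum(y == v)
    if (tq > 1) tie_term <- tie_term + tq * (tq - 1) * (2 * tq + 5)
  }
  list(s = s, var_s = (n * (n - 1) * (2 * n + 5) - tie_term) / 18)
}

# brute-force heatwave scanner: walk the series day by day
oracle_heatwaves <- function(dates, temps, thresh_by_doy, min_duration = 5) {
  hot <- temps > thresh_by_doy[doy365(dates)]
  events <- list()
  i <- 1
  n <- length(hot)
  while (i <= n) {
    if (hot[i]) {
      j <- i
      while (j < n && hot[j + 1]) j <- j + 1
      if (j - i + 1 >= min_duration) {
        events[[length(events) + 1]] <- c(start = i, end = j)
      }
      i <- j + 1
    } else i <- i + 1
  }
  events
}

# small shared config for fast cohort fixtures
tiny_config <- function(...) {
  sim_config(
    n_lakes = 4, seed = 11,
    start_date = "2003-01-01", end_date = "2009-12-31",
    climatology_start = "1985-01-01", climatology_end = "1999-12-31",
    ...
  )
}
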