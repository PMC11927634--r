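# Hemisphere-aware temporal aggregation and nonparametric trend estimation.
#
# All long-term rates in the pipeline are Theil-Sen slopes of annual summer
# medians, reported per decade, with significance from the Mann-Kendall test.
# Summer is Jul-Sep in the Northern Hemisphere and Jan-Mar in the Southern
# Hemisphere, which keeps the series snow/ice-free.

NH_SUMMER <- 7:9
SH_SUMMER <- 1:3

#' Annual summer medians
#'
#' Collapses a dated per-lake series to one summer median per year, using that
#' hemisphere's summer window (Jul-Sep north of the equator, Jan-Mar south of
#' it). The median is the robust annual estimator; years with no summer
#' observations are dropped.
#'
#' @param df data frame with columns `lake_id`, `date`, the value column named
#'   by `value_col`, and either a `hemisphere` column (`"N"`/`"S"`) or a
#'   `latitude` column from which it is derived.
#' @param value_col name of the value column (default `"value"`).
#' @return tibble with `lake_id`, `year`, `hemisphere`, `value`.
#' @export
summer_annual_median <- function(df, value_col = "value") {
  check_columns(df, c("lake_id", "date", value_col), "series")
  if (!"hemisphere" %in% names(df)) {
    check_columns(df, "latitude", "series (no hemisphere column)")
    df$hemisphere <- ifelse(df$latitude >= 0, "N", "S")
  }
  if (!all(df$hemisphere %in% c("N", "S"))) {
    abort("`hemisphere` must be \"N\" or \"S\"", class = "lakedo_error_validation")
  }
  df |>
    as_tibble() |>
    mutate(
      month = lubridate::month(.data$date),
      year = lubridate::year(.data$date)
    ) |>
    filter(
      (.data$hemisphere == "N" & .data$month %in% NH_SUMMER) |
        (.data$hemisphere == "S" & .data$month %in% SH_SUMMER)
    ) |>
    group_by(.data$lake_id, .data$hemisphere, .data$year) |>
    summarise(value = median(.data[[value_col]], na.rm = TRUE), .groups = "drop") |>
    filter(!is.na(.data$value)) |>
    select("lake_id", "year", "hemisphere", "value")
}

#' Theil-Sen slope
#'
#' Median of all pairwise slopes `(y_j - y_i) / (t_j - t_i)`, the standard
#' robust trend estimator (breakdown point ~29%).
#'
#' @param t numeric time axis (years).
#' @param y values.
#' @return slope in value units per unit of `t`, or `NA` with a warning when
#'   fewer than 2 distinct time points are available.
#' @export
#' @examples
#' theil_sen_slope(2003:2005, c(1, 2, 3))  # 1 per year
theil_sen_slope <- function(t, y) {
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  n <- length(t)
  if (n < 2 || length(unique(t)) < 2) {
    warn("Theil-Sen slope undefined: fewer than 2 distinct time points")
    return(NA_real_)
  }
  ij <- utils::combn(n, 2)
  dt <- t[ij[2, ]] - t[ij[1, ]]
  keep <- dt != 0
  median((y[ij[2, ]] - y[ij[1, ]])[keep] / dt[keep])
}

# exact null distribution of the Mann-Kendall S statistic for tie-free series:
# number of permutations of n items by inversion count (Mahonian numbers);
# S = n(n-1)/2 - 2 * inversions
mk_exact_pvalue <- function(s, n) {
  counts <- 1
  for (k in 2:n) counts <- round(stats::convolve(counts, rev(rep(1, k)), type = "open"))
  max_s <- n * (n - 1) / 2
  s_values <- max_s - 2 * (0:max_s)  # S for each inversion count
  probs <- counts / sum(counts)
  p <- sum(probs[abs(s_values) >= abs(s)])
  min(1, p)
}

#' Mann-Kendall trend test
#'
#' Nonparametric test for a monotonic trend based on
#' `S = sum_{i<j} sign(y_j - y_i)`. Uses the tie-corrected variance with a
#' normal approximation and continuity correction; for short tie-free series
#' (`n <= 10`) the exact null distribution of S is used instead.
#'
#' @param y values in time order.
#' @param alpha two-sided significance level (default 0.05).
#' @return one-row tibble with `s`, `var_s`, `p_value`, `significant`, `n`.
#' @export
mann_kendall <- function(y, alpha = 0.05) {
  y <- y[is.finite(y)]
  n <- length(y)
  if (n < 4) {
    abort("Mann-Kendall requires at least 4 values", class = "lakedo_error_validation")
  }
  ij <- utils::combn(n, 2)
  s <- sum(sign(y[ij[2, ]] - y[ij[1, ]]))
  ties <- table(y)
  ties <- ties[ties > 1]
  var_s <- (n * (n - 1) * (2 * n + 5) - sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  if (length(ties) == 0 && n <= 10) {
    p <- mk_exact_pvalue(s, n)
  } else if (var_s == 0) {
    p <- 1
  } else {
    z <- if (s > 0) (s - 1) / sqrt(var_s) else if (s < 0) (s + 1) / sqrt(var_s) else 0
    p <- 2 * pnorm(-abs(z))
  }
  tibble(s = s, var_s = var_s, p_value = p, significant = p < alpha, n = n)
}

#' Per-lake trend estimates on annual series
#'
#' Groups an annual table by lake and returns, per lake, the Theil-Sen slope
#' (scaled to per-decade units, the reporting convention for all rates here)
#' and the Mann-Kendall test.
#'
#' @param df tibble with `lake_id`, `year`, `value` (e.g. from
#'   [summer_annual_median()]).
#' @param alpha two-sided significance level (default 0.05).
#' @return tibble of class `lakedo_trends`: `lake_id`, `n_years`,
#'   `slope_per_decade`, `mk_s`, `p_value`, `significant`.
#' @export
trend_test <- function(df, alpha = 0.05) {
  check_columns(df, c("lake_id", "year", "value"), "annual series")
  out <- df |>
    as_tibble() |>
    group_by(.data$lake_id) |>
    summarise(
      n_years = sum(is.finite(.data$value)),
      slope_per_decade = if (n_years >= 2)
        10 * theil_sen_slope(.data$year, .data$value) else NA_real_,
      mk = if (n_years >= 4) list(mann_kendall(.data$value[order(.data$year)], alpha))
           else list(tibble(s = NA_real_, p_value = NA_real_, significant = NA)),
      .groups = "drop"
    ) |>
    tidyr::unnest_wider("mk") |>
    select("lake_id", "n_years", "slope_per_decade", mk_s = "s", "p_value", "significant")
  class(out) <- c("lakedo_trends", class(out))
  out
}
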