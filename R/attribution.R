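# Standardized path-coefficient attribution.
#
# A piecewise path model over per-lake annual series links climate drivers to
# DO through two routes: temperature, wind speed and pressure act on oxygen
# solubility (DOsol -> DO), and temperature acts on eutrophication
# (FAI -> DO). Every variable is standardized to mean 0 / SD 1 before
# fitting, so the least-squares coefficients are standardized path
# coefficients comparable across lakes and variables.

PATH_NAMES <- c("t_to_dosol", "wind_to_dosol", "pressure_to_dosol",
                "t_to_fai", "dosol_to_do", "fai_to_do")

standardize <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(NA_real_, length(x)))
  (x - mean(x)) / s
}

#' Fit the standardized path model for one lake
#'
#' Standardizes the annual series and fits the three structural sub-models by
#' least squares: `dosol ~ tair + wind + pressure`, `fai ~ tair`,
#' `do ~ dosol + fai`. Coefficients are reported per directed path. Variables
#' with zero variance get zero coefficients on their paths, flagged.
#'
#' @param annual tibble with columns `year`, `do`, `dosol`, `fai`, `tair`,
#'   `wind`, `pressure` (one row per year; at least 10 years).
#' @return tibble of class `lakedo_paths` with `path`, `coefficient`,
#'   `direction` (`"positive"` / `"negative"` / `"negligible"`, threshold
#'   `|coef| < 0.05`) and `degenerate` flag.
#' @export
fit_path_model <- function(annual) {
  check_columns(annual, c("year", "do", "dosol", "fai", "tair", "wind", "pressure"),
                "annual series")
  annual <- annual[complete.cases(annual[, c("do", "dosol", "fai", "tair", "wind", "pressure")]), ]
  if (nrow(annual) < 10) {
    abort("path model needs at least 10 annual values", class = "lakedo_error_validation")
  }
  z <- lapply(annual[, c("do", "dosol", "fai", "tair", "wind", "pressure")], standardize)
  degenerate_vars <- names(z)[vapply(z, function(v) anyNA(v), TRUE)]
  z <- lapply(z, function(v) if (anyNA(v)) rep(0, length(v)) else v)
  zd <- as.data.frame(z)
  safe_coefs <- function(formula, data, terms) {
    fit <- lm(formula, data = data)
    co <- coef(fit)[terms]
    co[is.na(co)] <- 0
    co
  }
  c_sol <- safe_coefs(dosol ~ tair + wind + pressure, zd, c("tair", "wind", "pressure"))
  c_fai <- safe_coefs(fai ~ tair, zd, "tair")
  c_do <- safe_coefs(do ~ dosol + fai, zd, c("dosol", "fai"))
  coefs <- c(c_sol, c_fai, c_do)
  # any path whose response or predictor is degenerate is zeroed
  path_vars <- list(
    t_to_dosol = c("tair", "dosol"), wind_to_dosol = c("wind", "dosol"),
    pressure_to_dosol = c("pressure", "dosol"), t_to_fai = c("tair", "fai"),
    dosol_to_do = c("dosol", "do"), fai_to_do = c("fai", "do")
  )
  degen <- vapply(path_vars, function(v) any(v %in% degenerate_vars), TRUE)
  coefs[degen] <- 0
  out <- tibble(
    path = PATH_NAMES,
    coefficient = unname(coefs),
    direction = dplyr::case_when(
      abs(coefs) < 0.05 ~ "negligible",
      coefs > 0 ~ "positive",
      TRUE ~ "negative"
    ),
    degenerate = unname(degen)
  )
  class(out) <- c("lakedo_paths", class(out))
  out
}

#' Fit path models across a cohort
#'
#' @param annual_cohort tibble with `lake_id` plus the columns required by
#'   [fit_path_model()]; lakes with fewer than 10 complete years are skipped
#'   with a message.
#' @return tibble with `lake_id`, `path`, `coefficient`, `direction`.
#' @export
fit_path_models <- function(annual_cohort) {
  check_columns(annual_cohort, "lake_id", "annual cohort")
  skipped <- 0L
  out <- annual_cohort |>
    as_tibble() |>
    tidyr::nest(data = -"lake_id") |>
    mutate(paths = purrr::map(.data$data, function(d) {
      tryCatch(fit_path_model(d), lakedo_error_validation = function(e) NULL)
    }))
  skipped <- sum(vapply(out$paths, is.null, TRUE))
  if (skipped > 0) inform(sprintf("fit_path_models: %d lake(s) skipped (too few complete years)", skipped))
  out |>
    filter(!vapply(.data$paths, is.null, TRUE)) |>
    select("lake_id", "paths") |>
    tidyr::unnest("paths")
}

#' Cohort-mean path contributions
#'
#' Per path, the mean standardized coefficient across lakes expressed as a
#' signed percent (x100), with counts of lakes by direction
#' (`|coef| < 0.05` is "negligible").
#'
#' @param models stacked per-lake coefficients from [fit_path_models()].
#' @return tibble with `path`, `mean_contribution_pct`, `n_positive`,
#'   `n_negative`, `n_negligible`, `n_lakes`.
#' @export
mean_contributions <- function(models) {
  check_columns(models, c("lake_id", "path", "coefficient"), "path models")
  models |>
    group_by(.data$path) |>
    summarise(
      mean_contribution_pct = 100 * mean(.data$coefficient),
      n_positive = sum(abs(.data$coefficient) >= 0.05 & .data$coefficient > 0),
      n_negative = sum(abs(.data$coefficient) >= 0.05 & .data$coefficient < 0),
      n_negligible = sum(abs(.data$coefficient) < 0.05),
      n_lakes = n(),
      .groups = "drop"
    )
}

#' Correlation between two per-lake rate vectors
#'
#' Pearson correlation (with two-sided p) between paired per-lake trend
#' rates, e.g. the DO rate against the solubility rate.
#'
#' @param df data frame holding the two rate columns.
#' @param col_a,col_b column names of the paired rates.
#' @return one-row tibble with `r`, `p_value`, `n`.
#' @export
rate_correlation <- function(df, col_a, col_b) {
  check_columns(df, c(col_a, col_b), "rates")
  ok <- is.finite(df[[col_a]]) & is.finite(df[[col_b]])
  if (sum(ok) < 3) {
    abort("rate correlation needs at least 3 complete pairs", class = "lakedo_error_validation")
  }
  ct <- cor.test(df[[col_a]][ok], df[[col_b]][ok], method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}
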