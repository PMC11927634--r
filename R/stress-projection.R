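# Low-oxygen stress metrics and scenario-driven DO projection.
#
# Stress is defined against the 6.0 mg/L threshold below which fish growth
# and food consumption decline: the stress frequency is the percentage of
# time steps with DO strictly below the threshold, and a lake-year is
# "stressed" when its annual mean DO falls below it.

#' Stress metrics for a cohort of DO series
#'
#' Per lake: percent of time steps with DO below `threshold` (strict) and
#' annual-mean stress flags. Cohort level: the annual count of stressed lakes
#' and its Theil-Sen trend per decade. The series' native time step (daily or
#' annual) is used as the frequency's time base and recorded.
#'
#' @param do_series tibble with `lake_id`, `date`, `do`.
#' @param threshold stress threshold, mg/L (default 6.0).
#' @return list of class `lakedo_stress` with `per_lake` (tibble `lake_id`,
#'   `n_steps`, `stress_freq_pct`, `ever_stressed`), `annual` (tibble
#'   `lake_id`, `year`, `mean_do`, `stressed`), `cohort` (tibble `year`,
#'   `n_stressed`), `trend_stressed_per_decade`, `threshold`, `time_base`.
#' @export
stress_metrics <- function(do_series, threshold = 6.0) {
  check_columns(do_series, c("lake_id", "date", "do"), "DO series")
  if (nrow(do_series) == 0) {
    abort("empty DO series", class = "lakedo_error_validation")
  }
  step_days <- do_series |>
    group_by(.data$lake_id) |>
    summarise(s = median(diff(as.numeric(sort(unique(.data$date))))), .groups = "drop")
  time_base <- if (median(step_days$s, na.rm = TRUE) >= 300) "annual"
               else if (median(step_days$s, na.rm = TRUE) <= 2) "daily" else "irregular"
  per_lake <- do_series |>
    group_by(.data$lake_id) |>
    summarise(
      n_steps = n(),
      stress_freq_pct = 100 * sum(.data$do < threshold) / n(),
      .groups = "drop"
    )
  annual <- do_series |>
    mutate(year = lubridate::year(.data$date)) |>
    group_by(.data$lake_id, .data$year) |>
    summarise(mean_do = mean(.data$do), .groups = "drop") |>
    mutate(stressed = .data$mean_do < threshold)
  per_lake <- per_lake |>
    left_join(annual |> group_by(.data$lake_id) |>
                summarise(ever_stressed = any(.data$stressed), .groups = "drop"),
              by = "lake_id")
  cohort <- annual |>
    group_by(.data$year) |>
    summarise(n_stressed = sum(.data$stressed), .groups = "drop")
  trend <- if (nrow(cohort) >= 2) 10 * theil_sen_slope(cohort$year, cohort$n_stressed) else NA_real_
  out <- list(per_lake = per_lake, annual = annual, cohort = cohort,
              trend_stressed_per_decade = trend,
              threshold = threshold, time_base = time_base)
  class(out) <- "lakedo_stress"
  out
}

#' Freeze water-colour features at recent-window means
#'
#' Projection forcing has no satellite water-colour stream, so FAI and hue
#' angle are held at their per-lake means over the trailing `window_years`
#' years of the historical record and applied to every projection date.
#'
#' @param features tibble with `lake_id`, `date`, `fai`, `hue_angle`.
#' @param window_years trailing window length (default 5).
#' @param end_year last historical year of the window (default: latest year
#'   present).
#' @return tibble with `lake_id`, `fai`, `hue_angle` (one row per lake with
#'   data in the window; lakes without any are dropped with a message).
#' @export
freeze_watercolour <- function(features, window_years = 5, end_year = NULL) {
  check_columns(features, c("lake_id", "date", "fai", "hue_angle"), "features")
  yr <- lubridate::year(features$date)
  if (is.null(end_year)) end_year <- max(yr)
  in_window <- yr > end_year - window_years & yr <= end_year
  n_lakes_all <- dplyr::n_distinct(features$lake_id)
  out <- features[in_window, ] |>
    group_by(.data$lake_id) |>
    summarise(fai = mean(.data$fai, na.rm = TRUE),
              hue_angle = mean(.data$hue_angle, na.rm = TRUE), .groups = "drop")
  dropped <- n_lakes_all - nrow(out)
  if (dropped > 0) inform(sprintf("freeze_watercolour: %d lake(s) have no features in the window and are excluded", dropped))
  out
}

#' Project DO under scenario forcing
#'
#' Runs the fitted model over each ensemble member's forcing (water-colour
#' features frozen via [freeze_watercolour()] or supplied directly), then
#' summarises the ensemble per scenario and time step as mean ± 2 SD across
#' members of the cohort-mean DO, with per-member and ensemble-mean Theil-Sen
#' trends per decade.
#'
#' @param bundle a fitted predictor (`lakedo_model` or [solubility_model()]).
#' @param forcing scenario forcing tibble from [sim_scenario_forcing()] (or
#'   the same shape read from files): `scenario`, `member`, `lake_id`, `date`
#'   plus the climate columns.
#' @param lakes lake metadata tibble (`lake_id`, `elevation`, `latitude`).
#' @param frozen_features per-lake frozen water features (`lake_id`, `fai`,
#'   `hue_angle`); lakes missing from it are dropped with a warning.
#' @return list of class `lakedo_projection` with `members` (per member/date
#'   cohort-mean DO), `ensemble` (per scenario/date mean, `sd`, `lo`, `hi`),
#'   `trends` (per member and ensemble-mean rates per decade).
#' @export
project_do <- function(bundle, forcing, lakes, frozen_features) {
  check_columns(forcing, c("scenario", "member", "lake_id", "date", "tair", "pressure",
                           "solar", "thermal", "precip", "wind_u", "wind_v"), "forcing")
  check_columns(frozen_features, c("lake_id", "fai", "hue_angle"), "frozen features")
  miss <- setdiff(unique(forcing$lake_id), frozen_features$lake_id)
  if (length(miss) > 0) {
    warn(sprintf("project_do: %d lake(s) dropped (no frozen water features)", length(miss)))
    forcing <- forcing[!forcing$lake_id %in% miss, ]
  }
  df <- forcing |>
    inner_join(frozen_features, by = "lake_id") |>
    inner_join(lakes[, c("lake_id", "elevation", "latitude")], by = "lake_id") |>
    mutate(wind_speed = sqrt(.data$wind_u^2 + .data$wind_v^2),
           abs_lat = abs(.data$latitude))
  df$do <- predict(bundle, df)
  members <- df |>
    group_by(.data$scenario, .data$member, .data$date) |>
    summarise(do = mean(.data$do), .groups = "drop")
  n_members <- members |> distinct(.data$scenario, .data$member) |> count(.data$scenario)
  if (any(n_members$n < 2)) {
    warn("fewer than 2 ensemble members in a scenario: no spread band for it")
  }
  ensemble <- members |>
    group_by(.data$scenario, .data$date) |>
    summarise(mean_do = mean(.data$do),
              sd_do = if (n() >= 2) sd(.data$do) else NA_real_,
              .groups = "drop") |>
    mutate(lo = .data$mean_do - 2 * .data$sd_do, hi = .data$mean_do + 2 * .data$sd_do)
  member_trends <- members |>
    mutate(year = lubridate::year(.data$date)) |>
    group_by(.data$scenario, .data$member, .data$year) |>
    summarise(do = mean(.data$do), .groups = "drop") |>
    group_by(.data$scenario, .data$member) |>
    summarise(rate_per_decade = 10 * theil_sen_slope(.data$year, .data$do), .groups = "drop")
  ens_trends <- ensemble |>
    mutate(year = lubridate::year(.data$date)) |>
    group_by(.data$scenario, .data$year) |>
    summarise(do = mean(.data$mean_do), .groups = "drop") |>
    group_by(.data$scenario) |>
    summarise(rate_per_decade = 10 * theil_sen_slope(.data$year, .data$do), .groups = "drop") |>
    mutate(member = "ensemble-mean", .before = 2)
  out <- list(members = members, ensemble = ensemble,
              trends = bind_rows(member_trends, ens_trends))
  class(out) <- "lakedo_projection"
  out
}
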