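# Atmospheric heatwave detection and counterfactual DO impact.
#
# A heatwave is a run of at least `min_duration` (default 5) consecutive days
# with air temperature strictly above the day-specific 90th percentile of the
# baseline climatology (default 1970-1999). Impacts on DO are quantified by
# re-predicting DO with heatwave-day temperatures replaced by the day-specific
# climatological mean, everything else held fixed.

#' Day-specific baseline climatology
#'
#' For each day-of-year slot 1-365 (leap days pooled into slot 59, see
#' [doy365()]), the mean and the 90th percentile (or `prob`-quantile) of all
#' baseline temperatures whose slot falls within `window_halfwidth` days.
#' The default halfwidth 0 pools strictly calendar-day values; a ±5-day window
#' is the common smoother in the heatwave literature and is available behind
#' the argument. Quantiles use linear interpolation between order statistics
#' (R type 7).
#'
#' @param baseline tibble with `date` and `tair` spanning the climatological
#'   period.
#' @param window_halfwidth pooling halfwidth in days (default 0).
#' @param prob exceedance percentile (default 0.9).
#' @return tibble of class `lakedo_climatology` with 365 rows: `doy`,
#'   `t_mean`, `t_thresh`, `n`.
#' @export
day_climatology <- function(baseline, window_halfwidth = 0, prob = 0.9) {
  check_columns(baseline, c("date", "tair"), "baseline series")
  n_years <- length(unique(lubridate::year(baseline$date)))
  if (n_years < 2) {
    abort("baseline must span at least 2 years", class = "lakedo_error_validation")
  }
  if (n_years < 10) warn("baseline spans fewer than 10 years: climatology will be noisy")
  doy <- doy365(baseline$date)
  by_day <- split(seq_along(doy), factor(doy, levels = 1:365))
  idx <- if (window_halfwidth == 0) by_day else {
    lapply(1:365, function(d) {
      win <- ((d - window_halfwidth):(d + window_halfwidth) - 1L) %% 365L + 1L
      unlist(by_day[win], use.names = FALSE)
    })
  }
  out <- tibble(
    doy = 1:365,
    t_mean = unname(vapply(idx, function(i) mean(baseline$tair[i]), 1)),
    t_thresh = unname(vapply(idx, function(i) quantile(baseline$tair[i], prob, names = FALSE, type = 7), 1)),
    n = unname(lengths(idx))
  )
  class(out) <- c("lakedo_climatology", class(out))
  out
}

#' Detect heatwave events
#'
#' Maximal runs of consecutive days with `tair` strictly above the
#' day-specific threshold; runs shorter than `min_duration` days (default 5)
#' are discarded. Runs may cross year boundaries. The input must be gap-free
#' daily data.
#'
#' @param temps tibble with `lake_id`, `date`, `tair` (daily, gap-free).
#' @param clim a `lakedo_climatology` from [day_climatology()].
#' @param min_duration minimum run length in days (default 5).
#' @return tibble of class `lakedo_events`: `lake_id`, `start`, `end`,
#'   `duration`, `exceedance` (mean degC above threshold over the event).
#' @export
detect_heatwaves <- function(temps, clim, min_duration = 5) {
  check_columns(temps, c("lake_id", "date", "tair"), "temperature series")
  stopifnot(inherits(clim, "lakedo_climatology"))
  temps <- arrange(temps, .data$date)
  gaps <- diff(as.numeric(temps$date))
  if (any(gaps != 1)) {
    abort("temperature series has gaps: fill or split before detection",
          class = "lakedo_error_validation")
  }
  thr <- clim$t_thresh[doy365(temps$date)]
  hot <- temps$tair > thr
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values & r$lengths >= min_duration)
  if (length(keep) == 0) {
    out <- tibble(lake_id = character(), start = as.Date(character()),
                  end = as.Date(character()), duration = integer(), exceedance = double())
  } else {
    # run sums of the exceedance via a cumulative sum over the anomaly
    cs <- cumsum(c(0, temps$tair - thr))
    len <- r$lengths[keep]
    out <- tibble(
      lake_id = temps$lake_id[1],
      start = temps$date[starts[keep]],
      end = temps$date[ends[keep]],
      duration = as.integer(len),
      exceedance = (cs[ends[keep] + 1] - cs[starts[keep]]) / len
    )
  }
  class(out) <- c("lakedo_events", class(out))
  out
}

#' Annual heatwave-day totals and their trend
#'
#' Expands events to days, totals them per calendar year (years with no event
#' count 0), and fits a Theil-Sen trend to the annual totals.
#'
#' @param events a `lakedo_events` tibble.
#' @param years integer vector of years the record covers (zero-filled years
#'   need to be known even when event-free).
#' @return list with `annual` (tibble `year`, `hw_days`), `mean_days_per_year`
#'   and `trend_days_per_year` (Theil-Sen slope of annual totals, days/yr per
#'   year).
#' @export
heatwave_duration_stats <- function(events, years) {
  stopifnot(length(years) >= 2)
  day_years <- if (nrow(events) == 0) integer() else {
    unlist(purrr::map2(events$start, events$end,
                       function(s, e) lubridate::year(seq(s, e, by = "day"))))
  }
  annual <- tibble(year = as.integer(years)) |>
    left_join(tibble(year = as.integer(day_years)) |> count(.data$year, name = "hw_days"),
              by = "year") |>
    mutate(hw_days = ifelse(is.na(.data$hw_days), 0L, .data$hw_days))
  list(
    annual = annual,
    mean_days_per_year = mean(annual$hw_days),
    trend_days_per_year = theil_sen_slope(annual$year, annual$hw_days)
  )
}

#' Instantaneous heatwave influence on DO
#'
#' For every heatwave day, DO is predicted twice with the fitted model: once
#' with the actual temperature and once with the day-specific climatological
#' mean temperature, all other features identical. The influence intensity of
#' a day is the signed percent difference
#' `100 * (DO_actual - DO_clim) / DO_clim` (negative = heatwave deoxygenation).
#' The mean intensity averages over heatwave days (`weight = "day"`, default)
#' or over per-event means (`weight = "event"`); the maximum is the value of
#' largest magnitude with its sign preserved.
#'
#' @param bundle a fitted predictor (`lakedo_model` or [solubility_model()]).
#' @param features per-date feature tibble for the lake (must contain every
#'   model feature, incl. `tair`, and a `date` column).
#' @param clim a `lakedo_climatology`.
#' @param events a `lakedo_events` tibble for the same lake.
#' @param weight `"day"` or `"event"` averaging (default `"day"`).
#' @return list of class `lakedo_influence` with `daily` (per-day tibble),
#'   `per_event` (per-event mean/max), `mean_intensity`, `max_intensity`,
#'   `n_excluded` (days dropped for non-positive counterfactual DO).
#' @export
influence_intensity <- function(bundle, features, clim, events,
                                weight = c("day", "event")) {
  weight <- match.arg(weight)
  stopifnot(inherits(clim, "lakedo_climatology"))
  if (nrow(events) == 0) {
    out <- list(daily = tibble(), per_event = tibble(),
                mean_intensity = NA_real_, max_intensity = NA_real_, n_excluded = 0L)
    class(out) <- "lakedo_influence"
    return(out)
  }
  event_days <- purrr::map_dfr(seq_len(nrow(events)), function(k) {
    tibble(event = k, date = seq(events$start[k], events$end[k], by = "day"))
  })
  rows <- inner_join(event_days, features, by = "date")
  cf <- rows
  cf$tair <- clim$t_mean[doy365(cf$date)]
  # one batched prediction per scenario across all events
  daily <- tibble(
    event = rows$event, date = rows$date,
    do_actual = predict(bundle, rows),
    do_clim = predict(bundle, cf)
  )
  bad <- daily$do_clim <= 0
  if (any(bad)) inform(sprintf("influence_intensity: %d day(s) excluded (non-positive counterfactual DO)", sum(bad)))
  daily <- daily[!bad, ]
  daily$intensity <- 100 * (daily$do_actual - daily$do_clim) / daily$do_clim
  per_event <- daily |>
    group_by(.data$event) |>
    summarise(mean_intensity = mean(.data$intensity),
              max_intensity = .data$intensity[which.max(abs(.data$intensity))],
              n_days = n(), .groups = "drop")
  mean_int <- if (weight == "day") mean(daily$intensity) else mean(per_event$mean_intensity)
  max_int <- daily$intensity[which.max(abs(daily$intensity))]
  out <- list(daily = daily, per_event = per_event,
              mean_intensity = mean_int, max_intensity = max_int,
              n_excluded = sum(bad))
  class(out) <- "lakedo_influence"
  out
}

#' Long-term heatwave impact on DO
#'
#' Predicts the full multi-year DO series under two scenarios: (A) actual
#' temperatures and (B) with every heatwave day's temperature replaced by the
#' day-specific climatological mean ("excluding heatwave events"). Reports the
#' scenario means, the relative difference normalised by the actual-scenario
#' value, and the Theil-Sen trend of annual mean DO under both.
#'
#' @param bundle a fitted predictor.
#' @param features per-date feature tibble (must contain every model feature
#'   and `date`).
#' @param clim a `lakedo_climatology`.
#' @param events a `lakedo_events` tibble.
#' @return one-row tibble with `mean_do_actual`, `mean_do_no_hw`,
#'   `longterm_mean_impact` (percent), `do_rate_actual`, `do_rate_no_hw`
#'   (mg/L per decade).
#' @export
longterm_impact <- function(bundle, features, clim, events) {
  stopifnot(inherits(clim, "lakedo_climatology"))
  hw_dates <- if (nrow(events) == 0) as.Date(character()) else {
    as.Date(unlist(purrr::map2(events$start, events$end,
                               function(s, e) as.list(seq(s, e, by = "day")))),
            origin = "1970-01-01")
  }
  cf <- features
  on_hw <- cf$date %in% hw_dates
  cf$tair[on_hw] <- clim$t_mean[doy365(cf$date[on_hw])]
  do_a <- predict(bundle, features)
  do_b <- predict(bundle, cf)
  yr <- lubridate::year(features$date)
  annual_a <- tapply(do_a, yr, mean)
  annual_b <- tapply(do_b, yr, mean)
  years <- as.integer(names(annual_a))
  tibble(
    mean_do_actual = mean(do_a),
    mean_do_no_hw = mean(do_b),
    longterm_mean_impact = 100 * (mean(do_a) - mean(do_b)) / mean(do_a),
    do_rate_actual = if (length(years) >= 2) 10 * theil_sen_slope(years, as.numeric(annual_a)) else NA_real_,
    do_rate_no_hw = if (length(years) >= 2) 10 * theil_sen_slope(years, as.numeric(annual_b)) else NA_real_,
    n_hw_days = sum(on_hw)
  )
}
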