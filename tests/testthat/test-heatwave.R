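baseline_series <- function(values_by_doy, years = 1990:1999) {
  dates <- seq(as.Date(paste0(min(years), "-01-01")),
               as.Date(paste0(max(years), "-12-31")), by = "day")
  tibble::tibble(lake_id = "L0001", date = dates,
                 tair = values_by_doy[doy365(dates)])
}

test_that("day climatology pools calendar days, handles leap days, matches order statistics", {
  # constant baseline -> threshold equals the constant everywhere
  clim <- day_climatology(baseline_series(rep(10, 365)))
  expect_equal(clim$t_thresh, rep(10, 365))
  expect_equal(clim$t_mean, rep(10, 365))
  expect_equal(nrow(clim), 365)
  # each calendar day's 30 values are 1..30: p90 equals the interpolated
  # order statistic of 1..30, checked against a sort-based computation
  years <- 1970:1999
  dates <- seq(as.Date("1970-01-01"), as.Date("1999-12-31"), by = "day")
  vals <- as.numeric(match(lubridate::year(dates), years))
  base <- tibble::tibble(lake_id = "L0001", date = dates, tair = vals)
  clim2 <- day_climatology(base)
  sorted_p90 <- function(x) { s <- sort(x); h <- (length(x) - 1) * 0.9 + 1
    s[floor(h)] + (h - floor(h)) * (s[floor(h) + 1] - s[floor(h)]) }
  # day 59 pools Feb 28 and leap-day Feb 29 values
  feb28 <- base$tair[doy365(base$date) == 59]
  expect_gt(length(feb28), 30)
  expect_equal(clim2$t_thresh[59], sorted_p90(feb28))
  expect_equal(clim2$t_thresh[100], sorted_p90(rep(1:30, 1)))
  expect_error(day_climatology(baseline_series(rep(10, 365), years = 1999)),
               class = "lakedo_error_validation")
  expect_warning(day_climatology(baseline_series(rep(10, 365), years = 1995:1999)))
})

test_that("detector enforces the 5-day persistence rule at the boundary", {
  clim <- day_climatology(baseline_series(rep(10, 365)))
  dates <- seq(as.Date("2005-01-01"), as.Date("2005-12-31"), by = "day")
  temps <- tibble::tibble(lake_id = "L0001", date = dates, tair = 5)
  # 4 consecutive exceedance days: no event
  t4 <- temps; t4$tair[100:103] <- 15
  expect_equal(nrow(detect_heatwaves(t4, clim)), 0)
  # 5 consecutive days: exactly one event of duration 5
  t5 <- temps; t5$tair[100:104] <- 15
  ev <- detect_heatwaves(t5, clim)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration, 5)
  expect_equal(ev$start, dates[100])
  expect_equal(ev$exceedance, 5)
  # exactly at the threshold does not exceed (strict inequality)
  t_eq <- temps; t_eq$tair[100:110] <- 10
  expect_equal(nrow(detect_heatwaves(t_eq, clim)), 0)
  # gaps are refused
  expect_error(detect_heatwaves(t5[-5, ], clim), class = "lakedo_error_validation")
})

test_that("detector reproduces the brute-force scanner on random series", {
  set.seed(14)
  years <- 1970:1999
  for (k in 1:60) {
    thresh <- rnorm(365, 10, 2)
    clim <- structure(
      tibble::tibble(doy = 1:365, t_mean = thresh - 2, t_thresh = thresh, n = 30L),
      class = c("lakedo_climatology", "tbl_df", "tbl", "data.frame"))
    dates <- seq(as.Date("2003-01-01"), as.Date("2023-12-31"), by = "day")
    temps <- tibble::tibble(lake_id = "L0001", date = dates,
                            tair = 10 + arima.sim(list(ar = 0.7), length(dates), sd = 2))
    got <- detect_heatwaves(temps, clim)
    want <- oracle_heatwaves(dates, temps$tair, thresh)
    expect_equal(nrow(got), length(want))
    if (length(want) > 0) {
      expect_equal(got$start, dates[vapply(want, `[[`, 1, "start")])
      expect_equal(got$end, dates[vapply(want, `[[`, 1, "end")])
    }
  }
})

test_that("generator-injected heatwave blocks are detected when they clear the threshold", {
  cfg <- sim_config(n_lakes = 2, seed = 8, heatwave_rate = 2, heatwave_amp = 10,
                    weather_sd = 1, warming_rate = 0)
  lakes <- sim_lakes(cfg)
  lake <- lakes[1, ]
  cl <- sim_climate(lake, cfg)
  base <- cl[cl$date <= cfg$climatology_end, ]
  study <- cl[cl$date >= cfg$start_date, ]
  clim <- day_climatology(base)
  ev <- detect_heatwaves(study, clim)
  thr <- clim$t_thresh[doy365(study$date)]
  # every injected block whose days all clear the day-specific threshold
  # must be inside a detected event
  r <- rle(study$heatwave_flag & study$tair > thr)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  full_blocks <- which(r$values & r$lengths >= 5)
  in_event <- function(d) any(ev$start <= d & d <= ev$end)
  for (b in full_blocks) {
    expect_true(all(vapply(study$date[starts[b]:ends[b]], in_event, TRUE)))
  }
  # and no detected day sits at or below threshold
  for (k in seq_len(nrow(ev))) {
    span <- study$date >= ev$start[k] & study$date <= ev$end[k]
    expect_true(all(study$tair[span] > thr[span]))
  }
})

test_that("duration stats aggregate annual heatwave days with their trend", {
  years <- 2003:2012
  none <- heatwave_duration_stats(
    structure(tibble::tibble(lake_id = character(), start = as.Date(character()),
                             end = as.Date(character()), duration = integer(),
                             exceedance = double()),
              class = c("lakedo_events", "tbl_df", "tbl", "data.frame")), years)
  expect_equal(none$annual$hw_days, rep(0L, 10))
  expect_equal(none$trend_days_per_year, 0)
  # one 7-day event per year -> 7 days/year, zero slope
  ev <- structure(tibble::tibble(
    lake_id = "L0001",
    start = as.Date(paste0(years, "-06-01")),
    end = as.Date(paste0(years, "-06-07")),
    duration = 7L, exceedance = 1), class = c("lakedo_events", "tbl_df", "tbl", "data.frame"))
  st <- heatwave_duration_stats(ev, years)
  expect_equal(st$annual$hw_days, rep(7L, 10))
  expect_equal(st$mean_days_per_year, 7)
  expect_equal(st$trend_days_per_year, 0)
})

test_that("counterfactual intensity is zero at identity and analytic for the solubility model", {
  clim <- day_climatology(baseline_series(rep(20, 365)))
  dates <- seq(as.Date("2005-06-01"), as.Date("2005-06-30"), by = "day")
  feats <- tibble::tibble(lake_id = "L0001", date = dates, tair = 20, pressure = 1,
                          solar = 200, thermal = 350, precip = 1, wind_speed = 2,
                          fai = 0.01, hue_angle = 100, elevation = 0, abs_lat = 45)
  ev5 <- structure(tibble::tibble(lake_id = "L0001", start = dates[10], end = dates[14],
                                  duration = 5L, exceedance = 5),
                   class = c("lakedo_events", "tbl_df", "tbl", "data.frame"))
  oracle <- solubility_model()
  # factual equals counterfactual -> exactly zero
  inf0 <- influence_intensity(oracle, feats, clim, ev5)
  expect_equal(inf0$mean_intensity, 0)
  expect_equal(inf0$max_intensity, 0)
  # +5 degC heatwave at 20 degC baseline: analytic solubility ratio
  feats_hw <- feats
  feats_hw$tair[10:14] <- 25
  inf5 <- influence_intensity(oracle, feats_hw, clim, ev5)
  want <- 100 * (o2_solubility(25) - o2_solubility(20)) / o2_solubility(20)
  expect_equal(inf5$mean_intensity, want, tolerance = 1e-6)
  expect_lt(inf5$mean_intensity, 0)
  expect_true(abs(inf5$max_intensity) >= abs(inf5$mean_intensity))
  # event-weighted and day-weighted agree for a single uniform event
  expect_equal(influence_intensity(oracle, feats_hw, clim, ev5, weight = "event")$mean_intensity,
               inf5$mean_intensity)
})

test_that("long-term impact is zero without events and negative under warm spikes", {
  clim <- day_climatology(baseline_series(rep(15, 365)))
  dates <- seq(as.Date("2003-01-01"), as.Date("2012-12-31"), by = "day")
  feats <- tibble::tibble(lake_id = "L0001", date = dates, tair = 15, pressure = 1,
                          solar = 200, thermal = 350, precip = 1, wind_speed = 2,
                          fai = 0.01, hue_angle = 100, elevation = 0, abs_lat = 45)
  no_ev <- structure(tibble::tibble(lake_id = character(), start = as.Date(character()),
                                    end = as.Date(character()), duration = integer(),
                                    exceedance = double()),
                     class = c("lakedo_events", "tbl_df", "tbl", "data.frame"))
  oracle <- solubility_model()
  lt0 <- longterm_impact(oracle, feats, clim, no_ev)
  expect_equal(lt0$longterm_mean_impact, 0)
  # warm spikes depress the actual-scenario mean DO
  feats_hw <- feats
  feats_hw$tair[100:120] <- 24
  ev <- structure(tibble::tibble(lake_id = "L0001", start = dates[100], end = dates[120],
                                 duration = 21L, exceedance = 9),
                  class = c("lakedo_events", "tbl_df", "tbl", "data.frame"))
  lt <- longterm_impact(oracle, feats_hw, clim, ev)
  expect_lt(lt$longterm_mean_impact, 0)
  expect_lt(lt$mean_do_actual, lt$mean_do_no_hw)
  # impact magnitude grows with spike amplitude
  feats_big <- feats
  feats_big$tair[100:120] <- 30
  lt_big <- longterm_impact(oracle, feats_big, clim, ev)
  expect_lt(lt_big$longterm_mean_impact, lt$longterm_mean_impact)
})
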