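# Synthetic-lake generator.
#
# Every downstream stage is exercised on lakes generated here: seasonal +
# trending climate forcing with injectable heatwave spikes, a latent trophic
# state driving reflectance whose FAI tracks it, "true" DO built as solubility
# modulated by a bounded trophic/photosynthesis factor, and sparse noisy
# matchup sampling. All draws are reproducible from a single seed, with
# independent per-lake substreams so lakes can be generated in any order.

SOLAR_MAX <- 400  # W/m2, normalisation for the photosynthesis factor

#' Synthetic-cohort configuration
#'
#' Bundles every knob of the generator with validated defaults. The defaults
#' are the study conditions used throughout: a 2003-2023 study period against
#' a 1970-1999 baseline climatology, 0.3 degC/decade warming, about 1.5
#' injected heatwave events per year at +4 degC, a slowly eutrophying trophic
#' state, 0.3 mg/L process noise on true DO and 0.3 mg/L in situ observation
#' error, and ~28.5 clear-sky reflectance samples per year.
#'
#' @param n_lakes number of lakes (>= 1).
#' @param start_date,end_date study period (Dates or strings).
#' @param climatology_start,climatology_end baseline period for the day-specific
#'   climatology.
#' @param warming_rate linear air-temperature trend, degC per decade.
#' @param heatwave_rate expected injected heatwave events per year.
#' @param heatwave_amp temperature added on injected heatwave days, degC.
#' @param trophic_trend latent trophic-state drift per decade (dimensionless).
#' @param noise_sd_do process noise on true DO, mg/L.
#' @param obs_noise_sd in situ DO observation error, mg/L (not stated in the
#'   source datasets; 0.3 mg/L is a typical sonde accuracy).
#' @param survey_rate expected in situ survey visits per year.
#' @param clear_rate expected clear-sky reflectance samples per year.
#' @param weather_sd SD of the AR(1) day-to-day temperature noise, degC.
#' @param ar1 AR(1) coefficient of the weather noise.
#' @param supersat_max bound of the photosynthesis factor (fraction; 0.15
#'   bounds supersaturation at +15%).
#' @param trophic_gain slope of the photosynthesis factor in the trophic state.
#' @param seed integer RNG seed.
#' @return validated list of class `lakedo_config`.
#' @export
sim_config <- function(n_lakes = 200,
                       start_date = "2003-01-01", end_date = "2023-12-31",
                       climatology_start = "1970-01-01", climatology_end = "1999-12-31",
                       warming_rate = 0.3, heatwave_rate = 1.5, heatwave_amp = 4,
                       trophic_trend = 0.1, noise_sd_do = 0.3, obs_noise_sd = 0.3,
                       survey_rate = 30, clear_rate = 28.5,
                       weather_sd = 2, ar1 = 0.7,
                       supersat_max = 0.15, trophic_gain = 1, seed = 42) {
  cfg <- list(
    n_lakes = n_lakes,
    start_date = as.Date(start_date), end_date = as.Date(end_date),
    climatology_start = as.Date(climatology_start),
    climatology_end = as.Date(climatology_end),
    warming_rate = warming_rate, heatwave_rate = heatwave_rate,
    heatwave_amp = heatwave_amp, trophic_trend = trophic_trend,
    noise_sd_do = noise_sd_do, obs_noise_sd = obs_noise_sd,
    survey_rate = survey_rate, clear_rate = clear_rate,
    weather_sd = weather_sd, ar1 = ar1,
    supersat_max = supersat_max, trophic_gain = trophic_gain,
    seed = as.integer(seed)
  )
  problems <- character()
  if (!is.numeric(n_lakes) || n_lakes < 1) problems <- c(problems, "n_lakes must be >= 1")
  if (cfg$end_date <= cfg$start_date) problems <- c(problems, "end_date must be after start_date")
  if (cfg$climatology_end <= cfg$climatology_start)
    problems <- c(problems, "climatology_end must be after climatology_start")
  if (noise_sd_do < 0 || obs_noise_sd < 0) problems <- c(problems, "noise SDs must be >= 0")
  if (heatwave_rate < 0 || heatwave_amp < 0) problems <- c(problems, "heatwave parameters must be >= 0")
  if (abs(ar1) >= 1) problems <- c(problems, "ar1 must satisfy |ar1| < 1")
  if (length(problems) > 0) {
    abort(paste0("invalid configuration: ", paste(problems, collapse = "; ")),
          class = "lakedo_error_config")
  }
  structure(cfg, class = "lakedo_config")
}

#' Generate lake metadata
#'
#' Lakes spanning both hemispheres and the tropics, with elevations in
#' `[0, 5000]` m (skewed low, as real lakes are) and areas of at least
#' 10 km^2 (the study universe).
#'
#' @param cfg a [sim_config()] object.
#' @return tibble with `lake_id`, `latitude`, `longitude`, `elevation`,
#'   `area`, `hemisphere`.
#' @export
sim_lakes <- function(cfg) {
  stopifnot(inherits(cfg, "lakedo_config"))
  n <- cfg$n_lakes
  withr_seed(cfg$seed, {
    lat <- runif(n, -55, 65)
    tibble(
      lake_id = sprintf("L%04d", seq_len(n)),
      latitude = lat,
      longitude = runif(n, -180, 180),
      elevation = 5000 * runif(n)^3,
      area = 10 + stats::rlnorm(n, log(40), 1),
      hemisphere = ifelse(lat >= 0, "N", "S")
    )
  })
}

# evaluate expr with a local RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

ar1_noise <- function(n, sd, phi) {
  if (sd == 0) return(rep(0, n))
  innov <- rnorm(n, 0, sd * sqrt(1 - phi^2))
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

#' Generate daily climate forcing for one lake
#'
#' Air temperature is a sinusoidal seasonal cycle (period 365.25 d, phase
#' flipped in the Southern Hemisphere), a linear warming trend, AR(1) weather
#' noise, and injected heatwave blocks of at least 5 consecutive days at
#' `+heatwave_amp` degC. Pressure follows the barometric formula for the
#' lake's elevation plus small AR(1) variability; solar and thermal radiation,
#' precipitation and wind components are seasonal/stochastic companions. The
#' series is gap-free from `climatology_start` (if `baseline = TRUE`) or
#' `start_date` through `end_date`.
#'
#' @param lake one-row lake tibble from [sim_lakes()].
#' @param cfg a [sim_config()] object.
#' @param baseline include the baseline climatology period (default `TRUE`).
#' @return tibble with `lake_id`, `date`, `tair`, `pressure`, `solar`,
#'   `thermal`, `precip`, `wind_u`, `wind_v`, `heatwave_flag`.
#' @export
sim_climate <- function(lake, cfg, baseline = TRUE) {
  stopifnot(inherits(cfg, "lakedo_config"), nrow(lake) == 1)
  from <- if (baseline) min(cfg$climatology_start, cfg$start_date) else cfg$start_date
  dates <- seq(from, cfg$end_date, by = "day")
  n <- length(dates)
  lat <- lake$latitude
  hemi <- if (lat >= 0) 1 else -1
  t_num <- as.numeric(dates)
  # NH seasonal peak ~ July 19
  phase <- as.numeric(as.Date("2000-07-19"))
  seas <- cos(2 * pi * (t_num - phase) / 365.25)
  base_t <- 27 - 0.35 * abs(lat) - 6.0 * lake$elevation / 1000
  amp_t <- 3 + 0.22 * abs(lat)
  years_since <- (t_num - as.numeric(as.Date("1970-01-01"))) / 365.25
  idx <- lake_index_of(lake$lake_id)

  withr_seed(lake_seed(cfg$seed, idx, 1L), {
    tair <- base_t + amp_t * hemi * seas + cfg$warming_rate * years_since / 10 +
      ar1_noise(n, cfg$weather_sd, cfg$ar1)
    # injected heatwave blocks
    hw_flag <- rep(FALSE, n)
    n_events <- rpois(1, cfg$heatwave_rate * n / 365.25)
    if (n_events > 0 && cfg$heatwave_amp > 0) {
      starts <- sample.int(n, n_events, replace = TRUE)
      durations <- 5 + rpois(n_events, 2)
      for (k in seq_len(n_events)) {
        span <- starts[k]:min(n, starts[k] + durations[k] - 1)
        if (length(span) >= 5) {
          tair[span] <- tair[span] + cfg$heatwave_amp
          hw_flag[span] <- TRUE
        }
      }
    }
    p0 <- pressure_from_elevation(lake$elevation)
    pressure <- p0 * (1 + 0.002 * seas) + ar1_noise(n, 0.002, cfg$ar1)
    solar_amp <- 0.5 * min(abs(lat) / 60, 1)
    solar <- pmax(0, SOLAR_MAX * (1 - 0.005 * abs(lat)) *
                    (0.65 + solar_amp * hemi * seas) +
                    ar1_noise(n, 15 * (cfg$weather_sd > 0), cfg$ar1))
    thermal <- 280 + 3 * tair + ar1_noise(n, 15 * (cfg$weather_sd > 0), cfg$ar1)
    precip <- if (cfg$weather_sd > 0) rgamma(n, shape = 0.3, scale = 10) else rep(2, n)
    wind_u <- 2 + ar1_noise(n, 1.2 * (cfg$weather_sd > 0), cfg$ar1)
    wind_v <- 1 + ar1_noise(n, 1.2 * (cfg$weather_sd > 0), cfg$ar1)
    tibble(
      lake_id = lake$lake_id, date = dates, tair = tair, pressure = pressure,
      solar = solar, thermal = thermal, precip = precip,
      wind_u = wind_u, wind_v = wind_v, heatwave_flag = hw_flag
    )
  })
}

#' Generate the latent trophic-state series for one lake
#'
#' A dimensionless eutrophication state: baseline level, linear drift of
#' `trophic_trend` per decade, a small summer-peaking seasonal cycle and AR(1)
#' noise, floored just above zero. It is the generator's ground truth; the
#' observable proxy is the FAI of the reflectance sampled from it.
#'
#' @param lake one-row lake tibble.
#' @param cfg a [sim_config()] object.
#' @return tibble with `lake_id`, `date`, `trophic` (daily over the study
#'   period).
#' @export
sim_trophic <- function(lake, cfg) {
  stopifnot(inherits(cfg, "lakedo_config"), nrow(lake) == 1)
  dates <- seq(cfg$start_date, cfg$end_date, by = "day")
  n <- length(dates)
  t_num <- as.numeric(dates)
  hemi <- if (lake$latitude >= 0) 1 else -1
  seas <- cos(2 * pi * (t_num - as.numeric(as.Date("2000-07-19"))) / 365.25)
  years <- (t_num - as.numeric(cfg$start_date)) / 365.25
  idx <- lake_index_of(lake$lake_id)
  withr_seed(lake_seed(cfg$seed, idx, 2L), {
    trophic <- 0.5 + cfg$trophic_trend * years / 10 + 0.15 * hemi * seas +
      ar1_noise(n, 0.1 * (cfg$weather_sd > 0), cfg$ar1)
    tibble(lake_id = lake$lake_id, date = dates, trophic = pmax(trophic, 0.01))
  })
}

#' Generate sparse multiband reflectance for one lake
#'
#' Samples clear-sky observation dates at `clear_rate` per year and emits
#' 5-band water-leaving reflectance (blue, green, red, NIR, SWIR) constructed
#' so that the FAI computed from the bands increases monotonically with the
#' latent trophic state and the hue angle shifts green-ward with it. Bands are
#' clipped to `[0, 1]`.
#'
#' @param lake one-row lake tibble.
#' @param cfg a [sim_config()] object.
#' @param trophic daily trophic series from [sim_trophic()]; generated if
#'   missing.
#' @param band_noise_sd per-band Gaussian noise SD (default 5e-4; 0 gives an
#'   exact deterministic mapping from the trophic state).
#' @return tibble with `lake_id`, `date`, `r_blue`, `r_green`, `r_red`,
#'   `r_nir`, `r_swir`, `latent_trophic`.
#' @export
sim_reflectance <- function(lake, cfg, trophic = NULL, band_noise_sd = 5e-4) {
  stopifnot(inherits(cfg, "lakedo_config"), nrow(lake) == 1)
  if (is.null(trophic)) trophic <- sim_trophic(lake, cfg)
  idx <- lake_index_of(lake$lake_id)
  withr_seed(lake_seed(cfg$seed, idx, 3L), {
    keep <- runif(nrow(trophic)) < cfg$clear_rate / 365.25
    tr <- trophic[keep, ]
    n <- nrow(tr)
    level <- tanh(cfg$trophic_gain * tr$trophic)
    bnoise <- function() if (band_noise_sd > 0) rnorm(n, 0, band_noise_sd) else 0
    r_red <- 0.025 + 0.010 * level + bnoise()
    r_swir <- 0.012 + bnoise()
    frac <- (FAI_NIR_NM - FAI_RED_NM) / (FAI_SWIR_NM - FAI_RED_NM)
    fai_true <- 0.002 + 0.03 * level
    r_nir <- r_red + (r_swir - r_red) * frac + fai_true + bnoise()
    r_blue <- 0.030 - 0.012 * level + bnoise()
    r_green <- 0.030 + 0.020 * level + bnoise()
    clip <- function(x) pmin(pmax(x, 0), 1)
    tibble(
      lake_id = tr$lake_id, date = tr$date,
      r_blue = clip(r_blue), r_green = clip(r_green), r_red = clip(r_red),
      r_nir = clip(r_nir), r_swir = clip(r_swir),
      latent_trophic = tr$trophic
    )
  })
}

#' Generate "true" daily DO for one lake
#'
#' `true_do(t) = DOsol(T(t), P(t)) * (1 + g(trophic, solar)) + noise`, with
#' `g = supersat_max * tanh(trophic_gain * trophic) * solar / solar_max` a
#' bounded photosynthesis factor (so supersaturation is capped at
#' `supersat_max`), solubility from [o2_solubility()] with air temperature
#' clamped to `[0, 40]` degC, and Gaussian process noise of SD `noise_sd_do`.
#' Setting `supersat_max = 0` and `noise_sd_do = 0` gives the pure-saturation
#' limit `true_do = DOsol` exactly.
#'
#' @param lake one-row lake tibble.
#' @param climate daily forcing from [sim_climate()].
#' @param trophic daily trophic series from [sim_trophic()].
#' @param cfg a [sim_config()] object.
#' @return tibble with `lake_id`, `date`, `true_do`, `do_sol_true`,
#'   `latent_trophic`, `heatwave_flag`.
#' @export
sim_true_do <- function(lake, climate, trophic, cfg) {
  stopifnot(inherits(cfg, "lakedo_config"), nrow(lake) == 1)
  joined <- inner_join(trophic, climate, by = c("lake_id", "date"))
  if (nrow(joined) < nrow(trophic)) {
    abort("climate and trophic series are misaligned: climate must cover every trophic date",
          class = "lakedo_error_alignment")
  }
  idx <- lake_index_of(lake$lake_id)
  withr_seed(lake_seed(cfg$seed, idx, 4L), {
    t_clamp <- pmin(pmax(joined$tair, 0), 40)
    do_sol <- o2_solubility(t_clamp, joined$pressure)
    g <- cfg$supersat_max * tanh(cfg$trophic_gain * joined$trophic) *
      pmin(joined$solar / SOLAR_MAX, 1)
    noise <- if (cfg$noise_sd_do > 0) rnorm(nrow(joined), 0, cfg$noise_sd_do) else 0
    tibble(
      lake_id = joined$lake_id, date = joined$date,
      true_do = pmax(do_sol * (1 + g) + noise, 0.05),
      do_sol_true = do_sol,
      latent_trophic = joined$trophic,
      heatwave_flag = joined$heatwave_flag
    )
  })
}

#' Simulate sparse in situ surveys and build matchups
#'
#' Draws survey dates at `survey_rate` per year, adds observation noise of SD
#' `obs_noise_sd` to the true DO, and pairs each observation with same-day
#' climate and with the nearest reflectance sample within a 2-day window
#' (ties broken towards the earlier sample) via [build_matchups()]. Water
#' features are the FAI and corrected hue angle of the matched sample; the
#' wind-speed feature is `sqrt(u^2 + v^2)`.
#'
#' @param lake one-row lake tibble.
#' @param truth output of [sim_true_do()].
#' @param reflectance output of [sim_reflectance()].
#' @param climate output of [sim_climate()].
#' @param cfg a [sim_config()] object.
#' @return matchup tibble (one row per matched observation) with the ten model
#'   features, `do_obs`, and provenance columns.
#' @export
sim_matchups <- function(lake, truth, reflectance, climate, cfg) {
  stopifnot(inherits(cfg, "lakedo_config"), nrow(lake) == 1)
  idx <- lake_index_of(lake$lake_id)
  obs <- withr_seed(lake_seed(cfg$seed, idx, 5L), {
    keep <- runif(nrow(truth)) < cfg$survey_rate / 365.25
    o <- truth[keep, c("lake_id", "date", "true_do")]
    o$do_obs <- o$true_do +
      (if (cfg$obs_noise_sd > 0) rnorm(nrow(o), 0, cfg$obs_noise_sd) else 0)
    o
  })
  feats <- reflectance |> fai() |> hue_angle()
  build_matchups(
    obs = obs, climate = climate,
    reflectance_features = feats[, c("lake_id", "date", "fai", "hue_angle")],
    lake = lake
  )
}

#' Generate a full synthetic cohort
#'
#' Runs the whole generator for every lake of the configuration and returns
#' the stacked tables. This is the entry point the pipeline and the test
#' suite use.
#'
#' @param cfg a [sim_config()] object.
#' @param baseline include baseline-period climate (default `TRUE`).
#' @return list with tibbles `lakes`, `climate`, `trophic`, `reflectance`,
#'   `truth`, `matchups`.
#' @export
sim_cohort <- function(cfg, baseline = TRUE) {
  stopifnot(inherits(cfg, "lakedo_config"))
  lakes <- sim_lakes(cfg)
  per_lake <- purrr::map(seq_len(nrow(lakes)), function(i) {
    lake <- lakes[i, ]
    climate <- sim_climate(lake, cfg, baseline = baseline)
    study <- climate[climate$date >= cfg$start_date, ]
    trophic <- sim_trophic(lake, cfg)
    reflectance <- sim_reflectance(lake, cfg, trophic)
    truth <- sim_true_do(lake, study, trophic, cfg)
    matchups <- sim_matchups(lake, truth, reflectance, study, cfg)
    list(climate = climate, trophic = trophic, reflectance = reflectance,
         truth = truth, matchups = matchups)
  })
  list(
    lakes = lakes,
    climate = bind_rows(purrr::map(per_lake, "climate")),
    trophic = bind_rows(purrr::map(per_lake, "trophic")),
    reflectance = bind_rows(purrr::map(per_lake, "reflectance")),
    truth = bind_rows(purrr::map(per_lake, "truth")),
    matchups = bind_rows(purrr::map(per_lake, "matchups"))
  )
}

#' Cohort of annual series with a known injected trend
#'
#' Direct generator for trend-recovery experiments: per lake, annual values
#' `intercept + slope_per_decade * (year - year_0)/10 + N(0, noise_sd)`.
#'
#' @param n_lakes number of lakes.
#' @param years integer vector of years.
#' @param slope_per_decade injected trend (value units per decade).
#' @param intercept mean level (default 9.5 mg/L).
#' @param noise_sd annual noise SD (default 0.3 mg/L, a realistic
#'   reconstruction error for an annual summer median).
#' @param seed RNG seed.
#' @return tibble with `lake_id`, `year`, `value`.
#' @export
sim_trend_cohort <- function(n_lakes, years, slope_per_decade, intercept = 9.5,
                             noise_sd = 0.3, seed = 42) {
  withr_seed(seed, {
    purrr::map_dfr(seq_len(n_lakes), function(i) {
      tibble(
        lake_id = sprintf("L%04d", i),
        year = years,
        value = intercept + slope_per_decade * (years - years[1]) / 10 +
          rnorm(length(years), 0, noise_sd)
      )
    })
  })
}

#' Cohort of annual driver/response series with known path weights
#'
#' Generator for attribution-recovery experiments. Standardized drivers
#' `t`, `wind`, `pressure` are iid N(0, 1); solubility is
#' `b_t * t + b_wind * wind + b_pressure * pressure + noise`, FAI is
#' `b_fai_t * t + noise`, and DO is `w_sol * dosol + w_fai * fai + noise`,
#' all renormalised downstream by the path-model fit.
#'
#' @param n_lakes number of replicate lakes.
#' @param n_years years per lake (default 21).
#' @param b_t,b_wind,b_pressure true driver-to-solubility weights (default
#'   -0.8, 0.2, 0.05: temperature dominates with a negative sign).
#' @param b_fai_t true temperature-to-FAI weight (default 0.4).
#' @param w_sol,w_fai true solubility and eutrophication weights on DO
#'   (default 0.8 and -0.3).
#' @param noise_sd residual SD on each structural equation (default 0.3).
#' @param seed RNG seed.
#' @return tibble with `lake_id`, `year`, `do`, `dosol`, `fai`, `tair`,
#'   `wind`, `pressure`.
#' @export
sim_path_cohort <- function(n_lakes, n_years = 21, b_t = -0.8, b_wind = 0.2,
                            b_pressure = 0.05, b_fai_t = 0.4,
                            w_sol = 0.8, w_fai = -0.3, noise_sd = 0.3, seed = 42) {
  withr_seed(seed, {
    purrr::map_dfr(seq_len(n_lakes), function(i) {
      t_ <- rnorm(n_years); wind <- rnorm(n_years); pres <- rnorm(n_years)
      dosol <- b_t * t_ + b_wind * wind + b_pressure * pres + rnorm(n_years, 0, noise_sd)
      fai_v <- b_fai_t * t_ + rnorm(n_years, 0, noise_sd)
      do_v <- w_sol * dosol + w_fai * fai_v + rnorm(n_years, 0, noise_sd)
      tibble(lake_id = sprintf("L%04d", i), year = 2003:(2003 + n_years - 1),
             do = do_v, dosol = dosol, fai = fai_v,
             tair = t_, wind = wind, pressure = pres)
    })
  })
}

#' Mock scenario forcing ensemble
#'
#' Emits per-member daily climate forcing for a projection horizon by running
#' the climate generator forward under scenario-specific warming rates and
#' member-specific seeds: a stand-in for a climate-model ensemble that keeps
#' the projection machinery fully testable offline.
#'
#' @param lakes lake tibble from [sim_lakes()].
#' @param cfg a [sim_config()] object (study-period settings are reused).
#' @param scenarios named numeric vector of warming rates (degC/decade), e.g.
#'   `c("SSP2-4.5" = 0.3, "SSP5-8.5" = 0.69)`.
#' @param n_members ensemble members per scenario (default 3).
#' @param horizon_start,horizon_end projection period.
#' @param step day step between emitted forcing dates (default 1).
#' @return tibble of forcing rows with `scenario`, `member` columns prepended.
#' @export
sim_scenario_forcing <- function(lakes, cfg,
                                 scenarios = c("SSP2-4.5" = 0.3, "SSP5-8.5" = 0.69),
                                 n_members = 3,
                                 horizon_start = "2024-01-01",
                                 horizon_end = "2050-12-31",
                                 step = 1) {
  stopifnot(inherits(cfg, "lakedo_config"), n_members >= 1)
  horizon_start <- as.Date(horizon_start); horizon_end <- as.Date(horizon_end)
  purrr::imap_dfr(as.list(scenarios), function(rate, scen) {
    purrr::map_dfr(seq_len(n_members), function(m) {
      cfg_m <- cfg
      cfg_m$warming_rate <- rate
      cfg_m$start_date <- horizon_start
      cfg_m$end_date <- horizon_end
      cfg_m$seed <- lake_seed(cfg$seed, m, salt = 7L + match(scen, names(scenarios)))
      class(cfg_m) <- "lakedo_config"
      forcing <- purrr::map_dfr(seq_len(nrow(lakes)), function(i) {
        sim_climate(lakes[i, ], cfg_m, baseline = FALSE)
      })
      if (step > 1) {
        keep_dates <- seq(horizon_start, horizon_end, by = step)
        forcing <- forcing[forcing$date %in% keep_dates, ]
      }
      mutate(forcing, scenario = scen, member = sprintf("%s-m%02d", scen, m),
             .before = 1)
    })
  })
}

#' Write cohort tables to CSV
#'
#' One CSV per entity (lakes, climate, trophic, reflectance, truth, matchups)
#' with fixed column order, suitable for re-loading any pipeline stage.
#'
#' @param cohort list from [sim_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(cohort), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(cohort[[nm]], p)
    p
  }, character(1))
  invisible(paths)
}
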