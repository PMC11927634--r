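test_that("configuration is validated and generation is seed-deterministic", {
  expect_error(sim_config(n_lakes = 0), class = "lakedo_error_config")
  expect_error(sim_config(start_date = "2010-01-01", end_date = "2005-01-01"),
               class = "lakedo_error_config")
  expect_error(sim_config(noise_sd_do = -1), class = "lakedo_error_config")
  cfg <- sim_config(n_lakes = 100, seed = 1)
  expect_identical(sim_lakes(cfg), sim_lakes(cfg))
  lake <- sim_lakes(cfg)[1, ]
  expect_identical(sim_climate(lake, cfg, baseline = FALSE),
                   sim_climate(lake, cfg, baseline = FALSE))
})

test_that("lake cohort spans hemispheres, tropics and the area floor", {
  cfg <- sim_config(n_lakes = 500, seed = 7)
  lakes <- sim_lakes(cfg)
  expect_gt(sum(lakes$latitude > 30), 0)    # NH temperate
  expect_gt(sum(lakes$latitude < -30), 0)   # SH temperate
  expect_gt(sum(abs(lakes$latitude) < 30), 0)  # tropics
  expect_true(all(lakes$area >= 10))
  expect_true(all(lakes$elevation >= 0 & lakes$elevation <= 5000))
  expect_identical(lakes$hemisphere, ifelse(lakes$latitude >= 0, "N", "S"))
})

test_that("noise-free climate is exactly periodic with period 365.25 days", {
  cfg <- tiny_config(warming_rate = 0, heatwave_rate = 0, weather_sd = 0)
  lake <- sim_lakes(cfg)[1, ]
  cl <- sim_climate(lake, cfg, baseline = FALSE)
  t_num <- as.numeric(cl$date)
  # the seasonal component at t and t + 4*365.25 days must agree exactly
  shift <- 1461L  # 4 * 365.25
  idx <- seq_len(nrow(cl) - shift)
  expect_equal(cl$tair[idx + shift], cl$tair[idx], tolerance = 1e-10)
  expect_true(all(diff(as.numeric(cl$date)) == 1))  # gap-free
})

test_that("warming trend is recovered by OLS on annual means", {
  cfg <- sim_config(n_lakes = 1, seed = 3, warming_rate = 0.3,
                    heatwave_rate = 0, weather_sd = 0)
  lake <- sim_lakes(cfg)[1, ]
  cl <- sim_climate(lake, cfg, baseline = FALSE)
  ann <- tapply(cl$tair, lubridate::year(cl$date), mean)
  yrs <- as.integer(names(ann))
  slope_decade <- 10 * unname(coef(lm(ann ~ yrs))[2])
  expect_lt(abs(slope_decade - 0.3), 0.05)
})

test_that("seasonal cycles are anti-phased across hemispheres", {
  cfg <- tiny_config(warming_rate = 0, heatwave_rate = 0, weather_sd = 0)
  north <- tibble::tibble(lake_id = "L0001", latitude = 40, longitude = 0,
                          elevation = 100, area = 50, hemisphere = "N")
  south <- dplyr::mutate(north, latitude = -40, hemisphere = "S")
  cl_n <- sim_climate(north, cfg, baseline = FALSE)
  cl_s <- sim_climate(south, cfg, baseline = FALSE)
  m_n <- tapply(cl_n$tair, lubridate::month(cl_n$date), mean)
  m_s <- tapply(cl_s$tair, lubridate::month(cl_s$date), mean)
  peak_gap <- abs(as.integer(names(which.max(m_n))) - as.integer(names(which.max(m_s))))
  expect_true(min(peak_gap, 12 - peak_gap) >= 5)
  # pressure decreases with elevation
  high <- dplyr::mutate(north, elevation = 3000)
  expect_lt(mean(sim_climate(high, cfg, baseline = FALSE)$pressure), mean(cl_n$pressure))
})

test_that("reflectance tracks the latent trophic state and stays in bounds", {
  cfg <- tiny_config(trophic_trend = 0.3)
  lake <- sim_lakes(cfg)[1, ]
  trophic <- sim_trophic(lake, cfg)
  refl <- sim_reflectance(lake, cfg, trophic, band_noise_sd = 0)
  bands <- as.matrix(refl[, c("r_blue", "r_green", "r_red", "r_nir", "r_swir")])
  expect_true(all(bands >= 0 & bands <= 1))
  f <- fai(refl)
  # noise off: FAI is strictly increasing in the latent trophic state
  ord <- order(refl$latent_trophic)
  expect_true(all(diff(f$fai[ord]) >= 0))
  # positive trophic trend lifts late-period FAI above early-period FAI
  yrs <- lubridate::year(refl$date)
  expect_gt(mean(f$fai[yrs >= max(yrs) - 1]), mean(f$fai[yrs <= min(yrs) + 1]))
  # sparse sampling near the configured rate
  n_years <- as.numeric(diff(range(trophic$date))) / 365.25
  expect_lt(abs(nrow(refl) / n_years - cfg$clear_rate), 10)
})

test_that("true DO equals solubility in the pure-saturation limit and warming lowers it", {
  cfg <- tiny_config(supersat_max = 0, noise_sd_do = 0)
  lake <- sim_lakes(cfg)[2, ]
  climate <- sim_climate(lake, cfg, baseline = FALSE)
  trophic <- sim_trophic(lake, cfg)
  truth <- sim_true_do(lake, climate, trophic, cfg)
  expect_equal(truth$true_do, truth$do_sol_true, tolerance = 1e-12)
  # monotone response to the trophic factor at fixed climate
  cfg2 <- tiny_config(supersat_max = 0.15, noise_sd_do = 0)
  t_hi <- dplyr::mutate(trophic, trophic = 2)
  t_lo <- dplyr::mutate(trophic, trophic = 0.1)
  expect_true(all(sim_true_do(lake, climate, t_hi, cfg2)$true_do >=
                  sim_true_do(lake, climate, t_lo, cfg2)$true_do))
  expect_error(sim_true_do(lake, climate[-(1:50), ], trophic, cfg),
               class = "lakedo_error_alignment")
})

test_that("warming-only cohort has negative DO trends for every lake", {
  cfg <- sim_config(n_lakes = 6, seed = 21, supersat_max = 0, noise_sd_do = 0,
                    weather_sd = 0, heatwave_rate = 0, warming_rate = 0.5)
  lakes <- sim_lakes(cfg)
  for (i in seq_len(nrow(lakes))) {
    lake <- lakes[i, ]
    climate <- sim_climate(lake, cfg, baseline = FALSE)
    truth <- sim_true_do(lake, climate, sim_trophic(lake, cfg), cfg)
    ann <- tapply(truth$true_do, lubridate::year(truth$date), mean)
    expect_lt(theil_sen_slope(as.integer(names(ann)), as.numeric(ann)), 0)
  }
})

test_that("matchups honour the 2-day reflectance window and scale with survey rate", {
  cfg <- tiny_config()
  lake <- sim_lakes(cfg)[1, ]
  climate <- sim_climate(lake, cfg, baseline = FALSE)
  trophic <- sim_trophic(lake, cfg)
  refl <- sim_reflectance(lake, cfg, trophic)
  truth <- sim_true_do(lake, climate, trophic, cfg)
  mu <- sim_matchups(lake, truth, refl, climate, cfg)
  expect_true(all(abs(as.numeric(mu$date - mu$t_reflectance)) <= 2))
  expect_true(all(mu$date == mu$t_climate))
  # matchup count roughly doubles with survey rate
  cfg2 <- tiny_config(survey_rate = 60)
  mu2 <- sim_matchups(lake, truth, refl, climate, cfg2)
  expect_gt(nrow(mu2) / nrow(mu), 1.4)
  # zero observation noise, matched rows reproduce the truth exactly
  cfg0 <- tiny_config(obs_noise_sd = 0)
  mu0 <- sim_matchups(lake, truth, refl, climate, cfg0)
  joined <- dplyr::inner_join(mu0, truth, by = c("lake_id", "date"))
  expect_equal(joined$do_obs, joined$true_do)
})
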