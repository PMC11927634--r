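make_obs <- function(dates, do = 8) {
  tibble::tibble(lake_id = "L0001", date = dates, do_obs = do)
}

fake_climate <- function(dates) {
  tibble::tibble(lake_id = "L0001", date = dates, tair = 15, pressure = 1,
                 solar = 200, thermal = 350, precip = 1, wind_u = 2, wind_v = 1)
}

fake_lake <- tibble::tibble(lake_id = "L0001", latitude = 45, longitude = 0,
                            elevation = 200, area = 50, hemisphere = "N")

test_that("matchup windows are honoured with the earlier-on-tie rule", {
  d0 <- as.Date("2010-06-10")
  obs <- make_obs(d0)
  climate <- fake_climate(seq(d0 - 5, d0 + 5, by = "day"))
  refl_same_day <- tibble::tibble(lake_id = "L0001", date = d0, fai = 0.01, hue_angle = 100)
  m <- build_matchups(obs, climate, refl_same_day, fake_lake)
  expect_equal(nrow(m), 1)
  # 3 days away -> excluded
  refl_far <- dplyr::mutate(refl_same_day, date = d0 + 3)
  expect_warning(m2 <- build_matchups(obs, climate, refl_far, fake_lake))
  expect_equal(nrow(m2), 0)
  # symmetric +/- 1 day candidates: the earlier is chosen
  refl_tie <- tibble::tibble(lake_id = "L0001", date = c(d0 - 1, d0 + 1),
                             fai = c(0.111, 0.999), hue_angle = c(1, 2))
  m3 <- build_matchups(obs, climate, refl_tie, fake_lake)
  expect_equal(m3$t_reflectance, d0 - 1)
  expect_equal(m3$fai, 0.111)
  # sub-daily timestamps: 1 h climate window enforced
  obs_t <- tibble::tibble(lake_id = "L0001",
                          date = as.POSIXct("2010-06-10 12:00", tz = "UTC"), do_obs = 8)
  clim_t <- dplyr::mutate(fake_climate(d0), date = as.POSIXct("2010-06-10 12:30", tz = "UTC"))
  refl_t <- dplyr::mutate(refl_same_day, date = as.POSIXct("2010-06-10 00:00", tz = "UTC"))
  expect_equal(nrow(build_matchups(obs_t, clim_t, refl_t, fake_lake)), 1)
  clim_late <- dplyr::mutate(clim_t, date = as.POSIXct("2010-06-10 13:30", tz = "UTC"))
  expect_warning(m4 <- build_matchups(obs_t, clim_late, refl_t, fake_lake))
  expect_equal(nrow(m4), 0)
  # wind speed is the vector magnitude
  expect_equal(m$wind_speed, sqrt(2^2 + 1^2))
})

test_that("feature scaling standardizes, rescales to [0,1], inverts and preserves out-of-range", {
  df <- tibble::tibble(a = c(0, 10), b = c(-5, 5))
  sc <- scale_features(df, cols = c("a", "b"))
  expect_equal(sc$data$a, c(0, 1))
  expect_equal(sc$data$b, c(0, 1))
  # round-trip inverse
  set.seed(2)
  df2 <- tibble::tibble(a = rnorm(50, 3, 2), b = runif(50, -9, 4))
  sc2 <- scale_features(df2, cols = c("a", "b"))
  back <- scale_invert(sc2$scaler, sc2$data)
  expect_equal(back$a, df2$a, tolerance = 1e-12)
  expect_equal(back$b, df2$b, tolerance = 1e-12)
  # rows outside the training range scale outside [0,1], unclipped
  outside <- scale_apply(sc2$scaler, tibble::tibble(a = max(df2$a) + 10, b = 0))
  expect_gt(outside$a, 1)
  # scaler fitted on a subset ignores the held-out rows
  sc3 <- scale_features(df2, cols = c("a", "b"), fit_rows = 1:25)
  expect_equal(max(scale_apply(sc3$scaler, df2[1:25, ])$a), 1)
  # zero-variance feature pinned at 0.5 with warning
  expect_warning(sc4 <- scale_features(tibble::tibble(a = rep(3, 5), b = 1:5),
                                       cols = c("a", "b")))
  expect_equal(sc4$data$a, rep(0.5, 5))
})

test_that("model recovery: solubility-driven matchups are learned almost exactly", {
  cfg <- sim_config(n_lakes = 40, seed = 5, start_date = "2003-01-01",
                    end_date = "2012-12-31", supersat_max = 0, noise_sd_do = 0,
                    obs_noise_sd = 0, survey_rate = 60)
  cohort <- sim_cohort(cfg, baseline = FALSE)
  m <- cohort$matchups
  set.seed(1)
  idx <- sample.int(nrow(m), round(0.7 * nrow(m)))
  bundle <- fit_do_model(m[idx, ], seed = 99)
  ev <- evaluate_do_model(bundle, m[-idx, ])
  expect_gt(ev$r2, 0.99)
  # determinism: same seed twice -> identical predictions
  bundle2 <- fit_do_model(m[idx, ], seed = 99)
  expect_identical(predict(bundle, m[-idx, ]), predict(bundle2, m[-idx, ]))
  # negative control: permuting the target destroys the fit
  m_perm <- m
  set.seed(3)
  m_perm$do_obs <- sample(m_perm$do_obs)
  bundle_perm <- fit_do_model(m_perm[idx, ], seed = 99)
  expect_lt(evaluate_do_model(bundle_perm, m_perm[-idx, ])$r2, 0.1)
  # temperature dominates the importance ranking on solubility-driven data
  expect_equal(tidy(bundle)$feature[1], "tair")
})

test_that("evaluation metrics match direct arithmetic and guard leakage", {
  y <- c(8, 10); yhat <- c(9, 9)
  met <- lakedo:::eval_metrics(y, yhat)
  expect_equal(met$mae, 1)
  expect_equal(met$rmse, 1)
  expect_equal(met$mre, (1 / 8 + 1 / 10) / 2)
  # perfect prediction and constant prediction
  expect_equal(lakedo:::eval_metrics(y, y)$r2, 1)
  expect_equal(lakedo:::eval_metrics(c(8, 10, 9), rep(9, 3))$r2, 0)
  # zero targets excluded from MRE with count
  met0 <- lakedo:::eval_metrics(c(0, 8), c(1, 9))
  expect_equal(met0$n_zero_excluded, 1)
  expect_equal(met0$mre, 1 / 8)
  # leakage guard
  train <- tibble::tibble(row_id = as.character(1:50),
                          tair = rnorm(50), pressure = 1, solar = 200, thermal = 350,
                          precip = 1, wind_speed = 2, fai = 0.01, hue_angle = 100,
                          elevation = 10, abs_lat = 45, do_obs = rnorm(50, 9))
  b <- fit_do_model(train, seed = 1)
  expect_error(evaluate_do_model(b, train[1:5, ]), class = "lakedo_error_leakage")
})

test_that("predict_do_series is deterministic, contract-stable and skips missing rows", {
  dates <- seq(as.Date("2010-06-01"), as.Date("2010-06-20"), by = "day")
  climate <- fake_climate(dates)
  train <- tibble::tibble(row_id = as.character(1:80),
                          tair = runif(80, 5, 25), pressure = 1, solar = 200, thermal = 350,
                          precip = 1, wind_speed = 2, fai = 0.01, hue_angle = 100,
                          elevation = 200, abs_lat = 45)
  train$do_obs <- o2_solubility(train$tair)
  b <- fit_do_model(train, seed = 1)
  wf <- tibble::tibble(date = dates, fai = 0.01, hue_angle = 100)
  s1 <- predict_do_series(b, fake_lake, climate, wf)
  expect_s3_class(s1, "lakedo_doseries")
  # identical inputs on two dates give identical predictions
  expect_equal(s1$do[1], s1$do[2])
  # unused extra columns do not change predictions
  s2 <- predict_do_series(b, fake_lake, dplyr::mutate(climate, junk = rnorm(20)), wf)
  expect_equal(s2$do, s1$do)
  # missing features are skipped with a message
  wf_gap <- wf; wf_gap$fai[3] <- NA
  expect_message(s3 <- predict_do_series(b, fake_lake, climate, wf_gap), "skipped")
  expect_equal(nrow(s3), 19)
})

test_that("gradient-boosted engine fits and interpolation fills sparse features", {
  train <- tibble::tibble(tair = runif(200, 5, 25), pressure = 1, solar = 200,
                          thermal = 350, precip = 1, wind_speed = 2, fai = 0.01,
                          hue_angle = 100, elevation = 200, abs_lat = 45)
  train$do_obs <- o2_solubility(train$tair)
  bx <- fit_do_model(train, engine = "xgboost", seed = 1)
  expect_gt(glance(bx)$train_r2, 0.9)
  # interpolation: linear between samples, constant beyond ends
  f <- tibble::tibble(date = as.Date(c("2010-01-01", "2010-01-05")),
                      fai = c(0, 0.04), hue_angle = c(100, 104))
  got <- interp_water_features(f, as.Date(c("2009-12-30", "2010-01-03", "2010-01-07")))
  expect_equal(got$fai, c(0, 0.02, 0.04))
  expect_equal(got$hue_angle, c(100, 102, 104))
  gapped <- interp_water_features(f, as.Date("2010-02-01"), max_gap_days = 5)
  expect_true(is.na(gapped$fai))
})
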