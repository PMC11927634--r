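# End-to-end pipeline: synthetic cohort -> water features -> DO model ->
# reconstruction -> trends -> heatwaves -> attribution -> stress -> projection.
#
# One config drives every stage; all constants of the analysis (90th
# percentile, 5-day persistence, 6.0 mg/L stress threshold, 1970-1999
# baseline, Jul-Sep / Jan-Mar summers) are surfaced as named keys with those
# defaults. Outputs are plain CSVs plus a JSON manifest, and a fixed seed
# makes the whole run byte-identical.

#' Pipeline configuration
#'
#' @param sim named list of [sim_config()] arguments (the synthetic cohort).
#' @param stages named logical vector enabling stages; names:
#'   `simulate`, `features`, `model`, `reconstruct`, `trends`, `heatwaves`,
#'   `attribution`, `stress`, `projection`.
#' @param alpha two-sided significance level for trend tests.
#' @param heatwave list: `percentile` (90), `min_duration` (5 days),
#'   `window_halfwidth` (0 days).
#' @param stress_threshold DO stress threshold, mg/L (6.0).
#' @param freeze_window trailing years for frozen water features (5).
#' @param train_frac training fraction of the matchups (0.7).
#' @param model list: `engine` (`"ranger"`), `grid` (`NULL` = single default
#'   fit), `num_trees` for the default fit (200 at pipeline scale).
#' @param impact_lakes number of lakes in the heatwave counterfactual
#'   subsample (20; the counterfactual re-predicts every heatwave day twice,
#'   so a subsample keeps the stage proportionate).
#' @param projection list: `scenarios` (named warming rates, degC/decade),
#'   `n_members`, `horizon_start`, `horizon_end`, `step` (days).
#' @param seed master seed.
#' @return validated list of class `lakedo_pipeline_config`.
#' @export
pipeline_config <- function(sim = list(),
                            stages = NULL,
                            alpha = 0.05,
                            heatwave = list(percentile = 90, min_duration = 5,
                                            window_halfwidth = 0),
                            stress_threshold = 6.0,
                            freeze_window = 5,
                            train_frac = 0.7,
                            model = list(engine = "ranger", grid = NULL, num_trees = 200L),
                            impact_lakes = 20,
                            projection = list(
                              scenarios = c("SSP2-4.5" = 0.3, "SSP5-8.5" = 0.69),
                              n_members = 2,
                              horizon_start = "2024-01-01",
                              horizon_end = "2043-12-31",
                              step = 10),
                            seed = 42) {
  all_stages <- c("simulate", "features", "model", "reconstruct", "trends",
                  "heatwaves", "attribution", "stress", "projection")
  st <- setNames(rep(TRUE, length(all_stages)), all_stages)
  if (!is.null(stages)) st[names(stages)] <- stages
  cfg <- list(sim = sim, stages = st, alpha = alpha, heatwave = heatwave,
              stress_threshold = stress_threshold, freeze_window = freeze_window,
              train_frac = train_frac, model = model, impact_lakes = impact_lakes,
              projection = projection, seed = as.integer(seed))
  v <- validate_config(cfg)
  if (!v$ok) {
    abort(paste0("invalid pipeline config: ", paste(v$errors, collapse = "; ")),
          class = "lakedo_error_config")
  }
  for (w in v$warnings) warn(w)
  structure(cfg, class = "lakedo_pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Checks every constant against its sane range and rejects unknown keys.
#' Returns an itemised report rather than throwing on content problems.
#'
#' @param config a config list (possibly not yet classed).
#' @return list with `ok` (logical), `errors` (character), `warnings`
#'   (character).
#' @export
validate_config <- function(config) {
  errors <- character(); warnings <- character()
  known <- c("sim", "stages", "alpha", "heatwave", "stress_threshold",
             "freeze_window", "train_frac", "model", "impact_lakes",
             "projection", "seed")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) errors <- c(errors, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  hw <- config$heatwave %||% list()
  pct <- hw$percentile %||% 90
  if (!is.numeric(pct) || pct <= 0 || pct >= 100) errors <- c(errors, "heatwave$percentile must be in (0, 100)")
  md <- hw$min_duration %||% 5
  if (!is.numeric(md) || md < 1) errors <- c(errors, "heatwave$min_duration must be >= 1")
  else if (md < 5) warnings <- c(warnings, "heatwave$min_duration below the 5-day persistence convention; accepted as a documented deviation")
  a <- config$alpha %||% 0.05
  if (!is.numeric(a) || a <= 0 || a >= 1) errors <- c(errors, "alpha must be in (0, 1)")
  thr <- config$stress_threshold %||% 6
  if (!is.numeric(thr) || thr <= 0) errors <- c(errors, "stress_threshold must be positive")
  tf <- config$train_frac %||% 0.7
  if (!is.numeric(tf) || tf <= 0 || tf >= 1) errors <- c(errors, "train_frac must be in (0, 1)")
  if (!is.null(config$sim)) {
    ok_sim <- tryCatch({ do.call(sim_config, config$sim); TRUE },
                       error = function(e) { errors <<- c(errors, conditionMessage(e)); FALSE })
  }
  list(ok = length(errors) == 0, errors = errors, warnings = warnings)
}

pipeline_summer_dates <- function(dates, hemisphere) {
  m <- lubridate::month(dates)
  if (hemisphere == "N") m %in% NH_SUMMER else m %in% SH_SUMMER
}

#' Run the pipeline end to end
#'
#' Executes every enabled stage in order, writes each stage's tables as CSV
#' under `out_dir`, plus a `manifest.json` (versions, seed, config hash, per-
#' stage row counts and headline numbers) and a `log.txt`. A stage whose
#' prerequisites were disabled aborts with the stage name. Outputs are
#' byte-identical across runs with the same config.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "lakedo_pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  say <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    inform(line)
  }
  st <- config$stages
  need <- function(stage, dep) {
    if (!st[[dep]]) abort(sprintf("stage '%s' requires disabled stage '%s'", stage, dep),
                          class = "lakedo_error_config")
  }
  res <- list()
  manifest <- list(
    package = "lakedo",
    package_version = as.character(utils::packageVersion("lakedo")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    stages = lapply(as.list(st), function(x) if (x) "run" else "skipped"),
    rows = list(), headline = list()
  )
  wr <- function(df, name) {
    readr::write_csv(df, file.path(out_dir, paste0(name, ".csv")))
    manifest$rows[[name]] <<- nrow(df)
  }

  sim_args <- config$sim
  sim_args$seed <- sim_args$seed %||% config$seed
  cfg <- do.call(sim_config, sim_args)

  if (st[["simulate"]]) {
    say("simulate: generating %d lakes (%s..%s)", cfg$n_lakes,
        format(cfg$start_date), format(cfg$end_date))
    res$cohort <- sim_cohort(cfg)
    say("simulate: %d matchup rows", nrow(res$cohort$matchups))
    wr(res$cohort$lakes, "lakes")
    wr(res$cohort$matchups, "matchups")
  }

  if (st[["features"]]) {
    need("features", "simulate")
    res$features <- res$cohort$reflectance |> fai() |> hue_angle() |>
      select("lake_id", "date", "fai", "hue_angle")
    say("features: %d reflectance samples", nrow(res$features))
    wr(res$features, "water_features")
  }

  if (st[["model"]]) {
    need("model", "simulate")
    m <- res$cohort$matchups
    n <- nrow(m)
    train_idx <- withr_seed(config$seed, sample.int(n, round(config$train_frac * n)))
    grid <- config$model$grid
    if (is.null(grid)) grid <- data.frame(num_trees = config$model$num_trees %||% 200L,
                                          max_depth = 0L, min_node = 5L)
    res$bundle <- fit_do_model(m[train_idx, ], engine = config$model$engine %||% "ranger",
                               grid = grid, seed = config$seed)
    res$eval <- evaluate_do_model(res$bundle, m[-train_idx, ])
    say("model: trained on %d, tested on %d matchups; test R2 %.3f, MAE %.3f",
        length(train_idx), n - length(train_idx), res$eval$r2, res$eval$mae)
    wr(as_tibble(res$eval), "model_evaluation")
    manifest$headline$rf_test_r2 <- res$eval$r2
    manifest$headline$rf_test_mae <- res$eval$mae
  }

  study_climate <- NULL
  if (st[["simulate"]]) {
    study_climate <- res$cohort$climate[res$cohort$climate$date >= cfg$start_date, ]
  }

  if (st[["reconstruct"]]) {
    need("reconstruct", "model"); need("reconstruct", "features")
    lakes <- res$cohort$lakes
    # assemble every lake's summer feature rows, then predict in one batch
    frame <- purrr::map_dfr(seq_len(nrow(lakes)), function(i) {
      lake <- lakes[i, ]
      clim <- study_climate[study_climate$lake_id == lake$lake_id, ]
      clim <- clim[pipeline_summer_dates(clim$date, lake$hemisphere), ]
      wf <- interp_water_features(
        res$features[res$features$lake_id == lake$lake_id, ], clim$date)
      clim |>
        left_join(wf, by = "date") |>
        mutate(wind_speed = sqrt(.data$wind_u^2 + .data$wind_v^2),
               elevation = lake$elevation, abs_lat = abs(lake$latitude))
    })
    frame <- frame[stats::complete.cases(frame[, res$bundle$features]), ]
    frame$do <- predict(res$bundle, frame)
    res$do_series <- add_oxygen_state(frame)[, c("lake_id", "date", "do", "do_sol", "do_sp")]
    class(res$do_series) <- c("lakedo_doseries", class(res$do_series))
    say("reconstruct: %d summer-day DO predictions", nrow(res$do_series))
    wr(res$do_series, "do_reconstruction")
  }

  if (st[["trends"]]) {
    need("trends", "reconstruct")
    lakes <- res$cohort$lakes[, c("lake_id", "hemisphere")]
    ann <- function(df, col) {
      summer_annual_median(left_join(df, lakes, by = "lake_id"), col)
    }
    res$annual_do <- ann(res$do_series, "do")
    res$trends_do <- trend_test(res$annual_do, config$alpha)
    res$trends_dosol <- trend_test(ann(res$do_series, "do_sol"), config$alpha)
    say("trends: median DO slope %.3f mg/L per decade; %.1f%% of lakes declining",
        median(res$trends_do$slope_per_decade, na.rm = TRUE),
        100 * mean(res$trends_do$slope_per_decade < 0, na.rm = TRUE))
    wr(res$trends_do, "trends_do")
    wr(res$trends_dosol, "trends_dosol")
    manifest$headline$median_do_trend_per_decade <-
      median(res$trends_do$slope_per_decade, na.rm = TRUE)
    manifest$headline$pct_lakes_declining <-
      100 * mean(res$trends_do$slope_per_decade < 0, na.rm = TRUE)
    manifest$headline$mean_do <- mean(res$annual_do$value)
  }

  if (st[["heatwaves"]]) {
    need("heatwaves", "simulate"); need("heatwaves", "model"); need("heatwaves", "features")
    lakes <- res$cohort$lakes
    prob <- (config$heatwave$percentile %||% 90) / 100
    hw <- purrr::map(seq_len(nrow(lakes)), function(i) {
      lake <- lakes[i, ]
      cl_all <- res$cohort$climate[res$cohort$climate$lake_id == lake$lake_id, ]
      base <- cl_all[cl_all$date >= cfg$climatology_start & cl_all$date <= cfg$climatology_end, ]
      clim <- day_climatology(base, config$heatwave$window_halfwidth %||% 0, prob)
      ev <- detect_heatwaves(cl_all[cl_all$date >= cfg$start_date, ], clim,
                             config$heatwave$min_duration %||% 5)
      list(clim = clim, events = ev)
    })
    res$events <- bind_rows(purrr::map(hw, "events"))
    yrs <- lubridate::year(cfg$start_date):lubridate::year(cfg$end_date)
    dstats <- purrr::map(hw, function(h) heatwave_duration_stats(h$events, yrs))
    res$hw_days_per_year <- mean(purrr::map_dbl(dstats, "mean_days_per_year"))
    say("heatwaves: %d events; mean %.1f heatwave days per lake-year",
        nrow(res$events), res$hw_days_per_year)
    # counterfactual impact on a subsample of lakes
    n_sub <- min(config$impact_lakes, nrow(lakes))
    res$influence <- purrr::map_dfr(seq_len(n_sub), function(i) {
      lake <- lakes[i, ]
      ev <- hw[[i]]$events
      if (nrow(ev) == 0) return(tibble())
      cl <- study_climate[study_climate$lake_id == lake$lake_id, ]
      wf <- interp_water_features(res$features[res$features$lake_id == lake$lake_id, ], cl$date)
      feats <- cl |> left_join(wf, by = "date") |>
        mutate(wind_speed = sqrt(.data$wind_u^2 + .data$wind_v^2),
               elevation = lake$elevation, abs_lat = abs(lake$latitude))
      inf <- influence_intensity(res$bundle, feats, hw[[i]]$clim, ev)
      lt <- longterm_impact(res$bundle, feats, hw[[i]]$clim, ev)
      tibble(lake_id = lake$lake_id, mean_intensity = inf$mean_intensity,
             max_intensity = inf$max_intensity,
             longterm_mean_impact = lt$longterm_mean_impact,
             do_rate_actual = lt$do_rate_actual, do_rate_no_hw = lt$do_rate_no_hw)
    })
    say("heatwaves: mean influence intensity %.2f%% over %d subsampled lakes",
        mean(res$influence$mean_intensity, na.rm = TRUE), n_sub)
    wr(res$events, "heatwave_events")
    wr(res$influence, "heatwave_influence")
    manifest$headline$heatwave_days_per_year <- res$hw_days_per_year
    manifest$headline$heatwave_mean_intensity_pct <-
      mean(res$influence$mean_intensity, na.rm = TRUE)
  }

  if (st[["attribution"]]) {
    need("attribution", "reconstruct"); need("attribution", "trends")
    lakes <- res$cohort$lakes[, c("lake_id", "hemisphere")]
    cl <- left_join(study_climate, lakes, by = "lake_id") |>
      mutate(wind = sqrt(.data$wind_u^2 + .data$wind_v^2))
    ann_of <- function(df, col, nm) {
      if (!"hemisphere" %in% names(df)) df <- left_join(df, lakes, by = "lake_id")
      summer_annual_median(df, col) |> rename(!!nm := "value") |> select(-"hemisphere")
    }
    annual <- ann_of(res$do_series, "do", "do") |>
      inner_join(ann_of(res$do_series, "do_sol", "dosol"), by = c("lake_id", "year")) |>
      inner_join(ann_of(cl, "tair", "tair"), by = c("lake_id", "year")) |>
      inner_join(ann_of(cl, "wind", "wind"), by = c("lake_id", "year")) |>
      inner_join(ann_of(cl, "pressure", "pressure"), by = c("lake_id", "year")) |>
      inner_join(
        res$features |> left_join(lakes, by = "lake_id") |>
          summer_annual_median("fai") |> rename(fai = "value") |> select(-"hemisphere"),
        by = c("lake_id", "year"))
    res$path_models <- fit_path_models(annual)
    res$contributions <- mean_contributions(res$path_models)
    res$rate_cor <- rate_correlation(
      inner_join(res$trends_do |> select("lake_id", do_rate = "slope_per_decade"),
                 res$trends_dosol |> select("lake_id", dosol_rate = "slope_per_decade"),
                 by = "lake_id"),
      "do_rate", "dosol_rate")
    sol_pct <- res$contributions$mean_contribution_pct[res$contributions$path == "dosol_to_do"]
    say("attribution: mean solubility path %.1f%%; DO~DOsol rate correlation R = %.2f",
        sol_pct, res$rate_cor$r)
    wr(res$path_models, "path_coefficients")
    wr(res$contributions, "path_contributions")
    wr(res$rate_cor, "rate_correlation")
    manifest$headline$solubility_path_contribution_pct <- sol_pct
    manifest$headline$fai_path_contribution_pct <-
      res$contributions$mean_contribution_pct[res$contributions$path == "fai_to_do"]
    manifest$headline$rate_correlation_r <- res$rate_cor$r
  }

  if (st[["stress"]]) {
    need("stress", "reconstruct")
    res$stress <- stress_metrics(res$do_series, config$stress_threshold)
    say("stress: %d lake(s) ever stressed; stressed-count trend %.2f per decade",
        sum(res$stress$per_lake$ever_stressed), res$stress$trend_stressed_per_decade)
    wr(res$stress$per_lake, "stress_per_lake")
    wr(res$stress$cohort, "stress_cohort")
    manifest$headline$n_lakes_ever_stressed <- sum(res$stress$per_lake$ever_stressed)
  }

  if (st[["projection"]]) {
    need("projection", "model"); need("projection", "features")
    pj <- config$projection
    forcing <- sim_scenario_forcing(res$cohort$lakes, cfg,
                                    scenarios = pj$scenarios, n_members = pj$n_members,
                                    horizon_start = pj$horizon_start,
                                    horizon_end = pj$horizon_end, step = pj$step)
    frozen <- freeze_watercolour(res$features, config$freeze_window)
    res$projection <- project_do(res$bundle, forcing, res$cohort$lakes, frozen)
    rates <- res$projection$trends |> filter(.data$member == "ensemble-mean")
    say("projection: ensemble-mean rates %s",
        paste(sprintf("%s %.3f", rates$scenario, rates$rate_per_decade), collapse = ", "))
    wr(res$projection$ensemble, "projection_ensemble")
    wr(res$projection$trends, "projection_trends")
    for (k in seq_len(nrow(rates))) {
      manifest$headline[[paste0("projected_rate_", gsub("[^0-9A-Za-z]", "", rates$scenario[k]))]] <-
        rates$rate_per_decade[k]
    }
  }

  writeLines(log_lines, file.path(out_dir, "log.txt"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
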