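# Matchup construction, feature scaling, and the tree-ensemble DO regressor.
#
# The production model is a random forest over ten features: six climate
# (air temperature, pressure, solar radiation, thermal radiation,
# precipitation, wind speed), two water-colour (FAI, hue angle) and two
# geographic (elevation, absolute latitude). A gradient-boosted alternative is
# retained for comparison. Features are standardized and min-max rescaled to
# [0, 1] on the training rows only.

DO_FEATURES <- c("tair", "pressure", "solar", "thermal", "precip", "wind_speed",
                 "fai", "hue_angle", "elevation", "abs_lat")

# nearest candidate index for each query time; ties broken to the earlier
# candidate. Both vectors numeric and cand sorted ascending.
nearest_index <- function(query, cand) {
  pos <- findInterval(query, cand)
  lo <- pmax(pos, 1L)
  hi <- pmin(pos + 1L, length(cand))
  gap_lo <- abs(query - cand[lo])
  gap_hi <- abs(query - cand[hi])
  # earlier candidate wins ties
  ifelse(pos < 1L, hi, ifelse(gap_lo <= gap_hi, lo, hi))
}

#' Build a matchup table under strict time windows
#'
#' Pairs each in situ DO observation with the climate record within
#' `clim_window_hours` (1 h; at daily forcing resolution this is a same-day
#' join) and the reflectance-feature record within `refl_window_days` (2 d).
#' When several candidates fall inside a window the one with the smallest
#' absolute time gap is chosen, ties broken towards the earlier record. If an
#' `obs` column `depth` is present, observations deeper than 1 m are dropped
#' (surface samples only).
#'
#' @param obs tibble with `lake_id`, `date` (Date or POSIXct) and `do_obs`;
#'   optional `depth` in metres.
#' @param climate forcing tibble with `lake_id`, `date` and the climate
#'   columns (`tair`, `pressure`, `solar`, `thermal`, `precip`, `wind_u`,
#'   `wind_v`).
#' @param reflectance_features tibble with `lake_id`, `date`, `fai`,
#'   `hue_angle` (3x3 window means that already passed [window_cv()]).
#' @param lake one-row lake tibble supplying `elevation` and `latitude`.
#' @param clim_window_hours climate matchup window (default 1).
#' @param refl_window_days reflectance matchup window (default 2).
#' @return matchup tibble with `row_id`, the ten model features, `do_obs` and
#'   the source timestamps; empty (with a warning) when nothing qualifies.
#' @export
build_matchups <- function(obs, climate, reflectance_features, lake,
                           clim_window_hours = 1, refl_window_days = 2) {
  check_columns(obs, c("lake_id", "date", "do_obs"), "obs")
  check_columns(climate, c("lake_id", "date", "tair", "pressure", "solar",
                           "thermal", "precip", "wind_u", "wind_v"), "climate")
  check_columns(reflectance_features, c("lake_id", "date", "fai", "hue_angle"),
                "reflectance features")
  if ("depth" %in% names(obs)) obs <- obs[is.na(obs$depth) | obs$depth <= 1, ]
  empty <- tibble(
    row_id = character(), lake_id = character(),
    date = as.Date(character()), t_climate = as.Date(character()),
    t_reflectance = as.Date(character()),
    tair = double(), pressure = double(), solar = double(), thermal = double(),
    precip = double(), wind_speed = double(), fai = double(),
    hue_angle = double(), elevation = double(), abs_lat = double(),
    do_obs = double()
  )
  if (nrow(obs) == 0 || nrow(climate) == 0 || nrow(reflectance_features) == 0) {
    warn("no qualifying matchups: empty table returned")
    return(empty)
  }
  daily <- inherits(obs$date, "Date") && inherits(climate$date, "Date")
  to_num <- function(d) if (inherits(d, "Date")) as.numeric(d) * 86400 else as.numeric(d)
  climate <- arrange(climate, .data$date)
  reflectance_features <- arrange(reflectance_features, .data$date)
  q <- to_num(obs$date)
  ct <- to_num(climate$date)
  rt <- to_num(reflectance_features$date)
  ci <- nearest_index(q, ct)
  ri <- nearest_index(q, rt)
  # at daily resolution the 1 h climate window means exact same-day
  clim_tol <- if (daily) 0 else clim_window_hours * 3600
  ok <- abs(q - ct[ci]) <= clim_tol &
    abs(q - rt[ri]) <= refl_window_days * 86400
  if (!any(ok)) {
    warn("no qualifying matchups: empty table returned")
    return(empty)
  }
  o <- obs[ok, ]; cl <- climate[ci[ok], ]; rf <- reflectance_features[ri[ok], ]
  tibble(
    row_id = paste0(o$lake_id, "-", format(o$date)),
    lake_id = o$lake_id,
    date = o$date,
    t_climate = cl$date,
    t_reflectance = rf$date,
    tair = cl$tair, pressure = cl$pressure, solar = cl$solar,
    thermal = cl$thermal, precip = cl$precip,
    wind_speed = sqrt(cl$wind_u^2 + cl$wind_v^2),
    fai = rf$fai, hue_angle = rf$hue_angle,
    elevation = lake$elevation, abs_lat = abs(lake$latitude),
    do_obs = o$do_obs
  )
}

#' Fit a feature scaler (standardize then min-max to \[0, 1\])
#'
#' Per feature: standardization to mean 0 / SD 1 followed by min-max rescaling
#' of the standardized values to `[0, 1]`, both fitted on the rows given by
#' `fit_rows` only and applied to every row. Values outside the training range
#' scale outside `[0, 1]` and are deliberately not clipped. Zero-variance
#' features are mapped to 0.5 with a warning.
#'
#' @param df data frame containing the feature columns.
#' @param cols feature column names (default the ten DO-model features).
#' @param fit_rows integer/logical row selector used to fit the scaler
#'   (default: all rows).
#' @return list with `data` (tibble of scaled rows) and `scaler` (a
#'   `lakedo_scaler` usable with [scale_apply()] and [scale_invert()]).
#' @export
scale_features <- function(df, cols = DO_FEATURES, fit_rows = NULL) {
  check_columns(df, cols, "feature table")
  fit <- if (is.null(fit_rows)) df[cols] else df[fit_rows, cols, drop = FALSE]
  if (nrow(fit) == 0) abort("`fit_rows` selects no rows", class = "lakedo_error_validation")
  center <- vapply(fit, mean, 1)
  spread <- vapply(fit, sd, 1)
  degenerate <- !is.finite(spread) | spread == 0
  if (any(degenerate)) {
    warn(paste0("zero-variance feature(s) left at 0.5: ",
                paste(cols[degenerate], collapse = ", ")))
    spread[degenerate] <- 1
  }
  z_fit <- sweep(sweep(as.matrix(fit), 2, center), 2, spread, "/")
  zmin <- apply(z_fit, 2, min)
  zmax <- apply(z_fit, 2, max)
  zrange <- zmax - zmin
  flat <- zrange == 0
  zrange[flat] <- 1
  scaler <- structure(
    list(cols = cols, center = center, spread = spread, zmin = zmin,
         zrange = zrange, degenerate = degenerate | flat),
    class = "lakedo_scaler"
  )
  list(data = scale_apply(scaler, df), scaler = scaler)
}

#' Apply a fitted feature scaler
#' @param scaler a `lakedo_scaler` from [scale_features()].
#' @param df data frame containing the scaler's feature columns.
#' @return tibble of scaled feature columns (same rows as `df`).
#' @export
scale_apply <- function(scaler, df) {
  stopifnot(inherits(scaler, "lakedo_scaler"))
  check_columns(df, scaler$cols, "feature table")
  z <- sweep(sweep(as.matrix(df[scaler$cols]), 2, scaler$center), 2, scaler$spread, "/")
  s <- sweep(sweep(z, 2, scaler$zmin), 2, scaler$zrange, "/")
  s[, scaler$degenerate] <- 0.5
  as_tibble(as.data.frame(s))
}

#' Invert a fitted feature scaler
#' @param scaler a `lakedo_scaler`.
#' @param df data frame of scaled feature columns.
#' @return tibble on the original feature scale.
#' @export
scale_invert <- function(scaler, df) {
  stopifnot(inherits(scaler, "lakedo_scaler"))
  check_columns(df, scaler$cols, "scaled table")
  z <- sweep(sweep(as.matrix(df[scaler$cols]), 2, scaler$zrange, "*"), 2, scaler$zmin, "+")
  x <- sweep(sweep(z, 2, scaler$spread, "*"), 2, scaler$center, "+")
  as_tibble(as.data.frame(x))
}

#' Default hyperparameter grid for the tree ensemble
#'
#' `num_trees` in {200, 500}, `max_depth` in {10, 20, unlimited (0)},
#' `min_node` in {1, 5}.
#'
#' @return data frame of 12 hyperparameter combinations.
#' @export
do_model_grid <- function() {
  expand.grid(num_trees = c(200L, 500L), max_depth = c(10L, 20L, 0L),
              min_node = c(1L, 5L))
}

#' Fit the DO retrieval model
#'
#' Fits a tree-ensemble regressor of observed DO on the ten model features,
#' with the feature scaler fitted on the training rows. With a multi-row
#' `grid`, hyperparameters are selected on an internal validation split
#' (fraction `valid_frac`, seeded) by RMSE and the winner is refitted on the
#' full training table. The default engine is the random forest (`ranger`);
#' `engine = "xgboost"` fits the gradient-boosted alternative used for
#' comparison. All fits are single-threaded and seeded, so results are
#' reproducible bit-for-bit.
#'
#' @param train matchup tibble (needs the feature columns and `target`;
#'   `row_id` is stored for leakage checks).
#' @param features feature column names (default the ten model features).
#' @param target target column name (default `"do_obs"`).
#' @param engine `"ranger"` (random forest, default) or `"xgboost"`.
#' @param grid data frame with columns `num_trees`, `max_depth`, `min_node`;
#'   `NULL` (default) fits a single configuration (500 trees, unlimited depth,
#'   min node 5).
#' @param seed RNG seed controlling the fit and the validation split.
#' @param valid_frac validation fraction for grid selection (default 0.25).
#' @return object of class `lakedo_model`: the fitted ensemble, the scaler,
#'   feature importance, and training metadata. Supports [predict()],
#'   [tidy()] (feature importance) and [glance()] (training metadata).
#' @export
fit_do_model <- function(train, features = DO_FEATURES, target = "do_obs",
                         engine = c("ranger", "xgboost"), grid = NULL,
                         seed = 42, valid_frac = 0.25) {
  engine <- match.arg(engine)
  check_columns(train, c(features, target), "training table")
  if (nrow(train) < 10) abort("need at least 10 training rows", class = "lakedo_error_validation")
  y <- train[[target]]
  degenerate_target <- sd(y) == 0
  if (degenerate_target) warn("constant target: model fitted but flagged degenerate")
  scaled <- scale_features(train, features)
  x <- scaled$data
  if (is.null(grid)) grid <- data.frame(num_trees = 500L, max_depth = 0L, min_node = 5L)
  grid_results <- NULL
  best <- grid[1, ]
  if (nrow(grid) > 1) {
    n <- nrow(train)
    val_idx <- withr_seed(seed, sample.int(n, max(1, round(valid_frac * n))))
    fit_idx <- setdiff(seq_len(n), val_idx)
    rmse <- vapply(seq_len(nrow(grid)), function(g) {
      f <- fit_engine(engine, x[fit_idx, ], y[fit_idx], grid[g, ], seed)
      sqrt(mean((predict_engine(engine, f, x[val_idx, ]) - y[val_idx])^2))
    }, 1)
    grid_results <- cbind(grid, valid_rmse = rmse)
    best <- grid[which.min(rmse), ]
  }
  fit <- fit_engine(engine, x, y, best, seed, importance = TRUE)
  bundle <- structure(
    list(engine = engine, fit = fit, scaler = scaled$scaler,
         features = features, target = target,
         train_row_ids = train[["row_id"]] %||% character(),
         meta = list(n_train = nrow(train), seed = seed, params = as.list(best),
                     grid_results = grid_results,
                     degenerate_target = degenerate_target)),
    class = "lakedo_model"
  )
  bundle$meta$train_metrics <- eval_metrics(y, predict(bundle, train))
  bundle
}

fit_engine <- function(engine, x, y, par, seed, importance = FALSE) {
  if (engine == "ranger") {
    ranger::ranger(
      x = as.data.frame(x), y = y,
      num.trees = par$num_trees, max.depth = par$max_depth,
      min.node.size = par$min_node,
      importance = if (importance) "permutation" else "none",
      seed = seed, num.threads = 1, verbose = FALSE
    )
  } else {
    xgboost::xgboost(
      x = as.matrix(x), y = y,
      nrounds = max(50L, par$num_trees %/% 4L),
      max_depth = if (par$max_depth == 0) 8L else par$max_depth,
      min_child_weight = par$min_node, learning_rate = 0.1,
      nthreads = 1, seed = seed, verbosity = 0
    )
  }
}

predict_engine <- function(engine, fit, x) {
  if (engine == "ranger") {
    predict(fit, data = as.data.frame(x), num.threads = 1)$predictions
  } else {
    predict(fit, as.matrix(x))
  }
}

#' Predict DO from a fitted model bundle
#' @param object a `lakedo_model`.
#' @param newdata data frame containing the bundle's feature columns (raw,
#'   unscaled; the stored scaler is applied internally).
#' @param ... unused.
#' @return numeric vector of DO predictions, mg/L.
#' @export
predict.lakedo_model <- function(object, newdata, ...) {
  x <- scale_apply(object$scaler, newdata)
  predict_engine(object$engine, object$fit, x)
}

eval_metrics <- function(y, yhat) {
  nz <- y != 0
  tibble(
    mae = mean(abs(yhat - y)),
    mre = mean(abs(yhat - y)[nz] / y[nz]),
    rmse = sqrt(mean((yhat - y)^2)),
    r2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2),
    n = length(y),
    n_zero_excluded = sum(!nz)
  )
}

#' Evaluate a fitted model on held-out matchups
#'
#' MAE, mean relative error, RMSE and R^2 on a disjoint test table. Rows whose
#' `row_id` also appears in the bundle's training rows trigger an error (train
#' /test leakage guard); rows with `do_obs = 0` are excluded from the MRE and
#' counted.
#'
#' @param bundle a `lakedo_model`.
#' @param test matchup tibble disjoint from the training rows.
#' @return one-row tibble of class `lakedo_eval` with `mae`, `mre`, `rmse`,
#'   `r2`, `n`, `n_zero_excluded`; the per-row predictions are attached as
#'   attribute `"predictions"`.
#' @export
evaluate_do_model <- function(bundle, test) {
  stopifnot(inherits(bundle, "lakedo_model"))
  if ("row_id" %in% names(test) && length(bundle$train_row_ids) > 0) {
    overlap <- intersect(test$row_id, bundle$train_row_ids)
    if (length(overlap) > 0) {
      abort(sprintf("train/test leakage: %d row(s) appear in both sets", length(overlap)),
            class = "lakedo_error_leakage")
    }
  }
  y <- test[[bundle$target]]
  yhat <- predict(bundle, test)
  out <- eval_metrics(y, yhat)
  class(out) <- c("lakedo_eval", class(out))
  attr(out, "predictions") <- tibble(observed = y, predicted = yhat)
  out
}

#' Predict a DO time series for one lake
#'
#' Applies a fitted bundle along a daily forcing series, joining water-colour
#' features by date (rows with missing features are skipped and counted in a
#' message), and appends solubility and saturation departure via
#' [add_oxygen_state()].
#'
#' @param bundle a `lakedo_model`.
#' @param lake one-row lake tibble (`elevation`, `latitude`).
#' @param climate daily forcing tibble for the lake.
#' @param water_features tibble with `date`, `fai`, `hue_angle` covering the
#'   requested dates (see [interp_water_features()] for filling sparse
#'   observations).
#' @return tibble of class `lakedo_doseries` with `lake_id`, `date`, `do`,
#'   `do_sol`, `do_sp`.
#' @export
predict_do_series <- function(bundle, lake, climate, water_features) {
  stopifnot(inherits(bundle, "lakedo_model"), nrow(lake) == 1)
  check_columns(water_features, c("date", "fai", "hue_angle"), "water features")
  df <- climate |>
    left_join(water_features[, c("date", "fai", "hue_angle")], by = "date") |>
    mutate(
      wind_speed = sqrt(.data$wind_u^2 + .data$wind_v^2),
      elevation = lake$elevation,
      abs_lat = abs(lake$latitude)
    )
  complete <- stats::complete.cases(df[, bundle$features])
  if (any(!complete)) {
    inform(sprintf("predict_do_series: %d row(s) skipped for missing features", sum(!complete)))
    df <- df[complete, ]
  }
  df$do <- predict(bundle, df)
  out <- add_oxygen_state(df)[, c("lake_id", "date", "do", "do_sol", "do_sp")]
  class(out) <- c("lakedo_doseries", class(out))
  out
}

#' Interpolate sparse water-colour features onto target dates
#'
#' Linear interpolation of FAI and hue angle between clear-sky observations,
#' held constant beyond the first/last sample. A maximum bridging gap can be
#' imposed; dates farther than `max_gap_days` from any sample get `NA`.
#'
#' @param features tibble with `date`, `fai`, `hue_angle` (sparse).
#' @param dates target `Date` vector.
#' @param max_gap_days maximum distance to the nearest sample (default `Inf`).
#' @return tibble with `date`, `fai`, `hue_angle` on the target dates.
#' @export
interp_water_features <- function(features, dates, max_gap_days = Inf) {
  check_columns(features, c("date", "fai", "hue_angle"), "water features")
  if (nrow(features) == 0) return(tibble(date = dates, fai = NA_real_, hue_angle = NA_real_))
  f <- arrange(features, .data$date)
  xs <- as.numeric(f$date)
  xt <- as.numeric(dates)
  interp1 <- function(v) approx(xs, v, xout = xt, rule = 2, ties = mean)$y
  out <- tibble(date = dates, fai = interp1(f$fai), hue_angle = interp1(f$hue_angle))
  if (is.finite(max_gap_days)) {
    gap <- vapply(xt, function(t0) min(abs(xs - t0)), 1)
    out$fai[gap > max_gap_days] <- NA_real_
    out$hue_angle[gap > max_gap_days] <- NA_real_
  }
  out
}

#' Pure-solubility reference predictor
#'
#' A predictor with the same interface as a fitted `lakedo_model` whose
#' prediction is exactly the oxygen solubility at the row's air temperature
#' (clamped to `[0, 40]` degC) and pressure. Used as a physically transparent
#' reference model in counterfactual and projection analyses.
#'
#' @return object of class `lakedo_o2_model`.
#' @export
solubility_model <- function() {
  structure(list(features = c("tair", "pressure")), class = "lakedo_o2_model")
}

#' @rdname solubility_model
#' @param object a `lakedo_o2_model`.
#' @param newdata data frame with `tair` and `pressure` columns.
#' @param ... unused.
#' @export
predict.lakedo_o2_model <- function(object, newdata, ...) {
  o2_solubility(pmin(pmax(newdata$tair, 0), 40), newdata$pressure)
}
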