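# broom-style tidiers for fitted objects.

#' Tidy a fitted DO model: feature importance
#'
#' @param x a `lakedo_model`.
#' @param ... unused.
#' @return tibble with `feature`, `importance` (permutation importance for the
#'   random forest, gain for the gradient-boosted engine), sorted descending.
#' @method tidy lakedo_model
#' @export
tidy.lakedo_model <- function(x, ...) {
  imp <- if (x$engine == "ranger") {
    v <- ranger::importance(x$fit)
    tibble(feature = names(v), importance = unname(v))
  } else {
    m <- xgboost::xgb.importance(model = x$fit)
    tibble(feature = m$Feature, importance = m$Gain)
  }
  arrange(imp, dplyr::desc(.data$importance))
}

#' Glance at a fitted DO model
#'
#' @param x a `lakedo_model`.
#' @param ... unused.
#' @return one-row tibble with engine, hyperparameters, n_train, seed and
#'   training metrics.
#' @method glance lakedo_model
#' @export
glance.lakedo_model <- function(x, ...) {
  dplyr::bind_cols(
    tibble(engine = x$engine, n_train = x$meta$n_train, seed = x$meta$seed,
           degenerate_target = x$meta$degenerate_target),
    as_tibble(x$meta$params),
    x$meta$train_metrics |>
      rename(train_mae = "mae", train_mre = "mre", train_rmse = "rmse",
             train_r2 = "r2") |>
      select("train_mae", "train_mre", "train_rmse", "train_r2")
  )
}

#' Tidy a stress summary: per-lake table
#' @param x a `lakedo_stress`.
#' @param ... unused.
#' @return the per-lake tibble.
#' @method tidy lakedo_stress
#' @export
tidy.lakedo_stress <- function(x, ...) x$per_lake

#' Glance at a stress summary
#' @param x a `lakedo_stress`.
#' @param ... unused.
#' @return one-row tibble with cohort-level stress numbers.
#' @method glance lakedo_stress
#' @export
glance.lakedo_stress <- function(x, ...) {
  tibble(
    threshold = x$threshold,
    time_base = x$time_base,
    n_lakes = nrow(x$per_lake),
    n_ever_stressed = sum(x$per_lake$ever_stressed),
    mean_stress_freq_pct = mean(x$per_lake$stress_freq_pct),
    trend_stressed_per_decade = x$trend_stressed_per_decade
  )
}

#' Tidy a projection: ensemble summary
#' @param x a `lakedo_projection`.
#' @param ... unused.
#' @return the per-scenario/date ensemble tibble.
#' @method tidy lakedo_projection
#' @export
tidy.lakedo_projection <- function(x, ...) x$ensemble

#' Glance at a projection: per-scenario ensemble-mean rates
#' @param x a `lakedo_projection`.
#' @param ... unused.
#' @return tibble with `scenario` and `rate_per_decade`.
#' @method glance lakedo_projection
#' @export
glance.lakedo_projection <- function(x, ...) {
  x$trends |> filter(.data$member == "ensemble-mean") |> select(-"member")
}

#' Tidy an influence report: per-event intensities
#' @param x a `lakedo_influence`.
#' @param ... unused.
#' @return the per-event tibble.
#' @method tidy lakedo_influence
#' @export
tidy.lakedo_influence <- function(x, ...) x$per_event

#' Glance at an influence report
#' @param x a `lakedo_influence`.
#' @param ... unused.
#' @return one-row tibble with mean/max intensity and exclusion count.
#' @method glance lakedo_influence
#' @export
glance.lakedo_influence <- function(x, ...) {
  tibble(mean_intensity = x$mean_intensity, max_intensity = x$max_intensity,
         n_events = nrow(x$per_event), n_excluded = x$n_excluded)
}
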