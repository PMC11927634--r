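# ggplot2 graphics for the main result types.

#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_histogram
#'   geom_ribbon geom_col geom_abline geom_vline labs facet_wrap autoplot
NULL

#' @export
ggplot2::autoplot

#' Plot a reconstructed DO series
#'
#' DO and solubility against time; the gap between the two curves is the
#' saturation departure.
#'
#' @param object a `lakedo_doseries`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot lakedo_doseries
#' @export
autoplot.lakedo_doseries <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object)[, c("lake_id", "date", "do", "do_sol")],
                            c("do", "do_sol"), names_to = "series")
  ggplot(df, aes(x = .data$date, y = .data$value, colour = .data$series)) +
    geom_line(alpha = 0.8) +
    facet_wrap(~lake_id, scales = "free_y") +
    labs(x = NULL, y = "dissolved oxygen (mg/L)", colour = NULL,
         title = "Reconstructed DO and solubility")
}

#' Plot a cohort of trend estimates
#'
#' Histogram of per-lake slopes (per decade) with the zero line.
#'
#' @param object a `lakedo_trends` tibble.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot lakedo_trends
#' @export
autoplot.lakedo_trends <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$slope_per_decade)) +
    geom_histogram(bins = 40, fill = "steelblue", colour = "white") +
    geom_vline(xintercept = 0, linetype = 2) +
    labs(x = "Theil-Sen slope (units per decade)", y = "lakes",
         title = "Per-lake trend distribution")
}

#' Plot model evaluation: observed vs predicted
#'
#' @param object a `lakedo_eval` (with attached predictions).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot lakedo_eval
#' @export
autoplot.lakedo_eval <- function(object, ...) {
  preds <- attr(object, "predictions")
  ggplot(preds, aes(x = .data$observed, y = .data$predicted)) +
    geom_point(alpha = 0.2, size = 0.6) +
    geom_abline(slope = 1, intercept = 0, colour = "red") +
    labs(x = "observed DO (mg/L)", y = "predicted DO (mg/L)",
         title = sprintf("Held-out evaluation: R2 = %.2f, MAE = %.2f mg/L",
                         object$r2, object$mae))
}

#' Plot a scenario projection with ensemble spread
#'
#' Ensemble-mean DO per scenario with a ±2 SD ribbon across members.
#'
#' @param object a `lakedo_projection`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot lakedo_projection
#' @export
autoplot.lakedo_projection <- function(object, ...) {
  ggplot(object$ensemble, aes(x = .data$date, y = .data$mean_do,
                              colour = .data$scenario, fill = .data$scenario)) +
    geom_ribbon(aes(ymin = .data$lo, ymax = .data$hi), alpha = 0.2, colour = NA) +
    geom_line() +
    labs(x = NULL, y = "cohort-mean DO (mg/L)", colour = NULL, fill = NULL,
         title = "Projected DO (ensemble mean ± 2 SD)")
}

#' Plot mean path contributions
#'
#' Signed mean standardized path coefficients (as percent) across a cohort.
#'
#' @param contributions tibble from [mean_contributions()].
#' @return a ggplot.
#' @export
plot_contributions <- function(contributions) {
  check_columns(contributions, c("path", "mean_contribution_pct"), "contributions")
  ggplot(contributions,
         aes(x = stats::reorder(.data$path, .data$mean_contribution_pct),
             y = .data$mean_contribution_pct,
             fill = .data$mean_contribution_pct > 0)) +
    geom_col(show.legend = FALSE) +
    ggplot2::coord_flip() +
    labs(x = NULL, y = "mean standardized path coefficient (%)",
         title = "Cohort-mean path contributions")
}
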