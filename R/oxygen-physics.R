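# Oxygen solubility, saturation departure and seasonal amplitude.
#
# Solubility uses the Benson-Krause freshwater equilibrium equation (the USGS
# standard), with the standard vapour-pressure / partial-molar-volume pressure
# correction. Salinity is taken as zero throughout: the analysis is restricted
# to surface freshwater.

# Benson-Krause unit standard atmospheric concentration, mg/L at 1 atm
bk_unit_solubility <- function(temp_c) {
  tk <- temp_c + 273.15
  exp(-139.34411 + 1.575701e5 / tk - 6.642308e7 / tk^2 +
        1.2438e10 / tk^3 - 8.621949e11 / tk^4)
}

#' Oxygen solubility in fresh water
#'
#' Equilibrium dissolved-oxygen concentration at the given air temperature and
#' barometric pressure (Benson-Krause equation with the USGS pressure
#' correction; zero salinity). Strictly decreasing in temperature and
#' increasing in pressure over the supported range.
#'
#' @param temp_c water/air temperature in degrees Celsius; must lie in
#'   `[-2, 45]`.
#' @param pressure_atm barometric pressure in atmospheres (default 1).
#' @return solubility in mg/L, vectorised over the inputs.
#' @export
#' @examples
#' o2_solubility(20)            # ~9.09 mg/L
#' o2_solubility(0)             # ~14.62 mg/L
#' o2_solubility(20, 0.85)      # high-altitude lake
o2_solubility <- function(temp_c, pressure_atm = 1) {
  if (!is.numeric(temp_c) || anyNA(temp_c)) {
    abort("`temp_c` must be numeric with no missing values", class = "lakedo_error_validation")
  }
  if (any(temp_c < -2 | temp_c > 45)) {
    abort("`temp_c` outside the supported range [-2, 45] degC", class = "lakedo_error_validation")
  }
  if (any(pressure_atm <= 0)) {
    abort("`pressure_atm` must be positive", class = "lakedo_error_validation")
  }
  tk <- temp_c + 273.15
  c_star <- bk_unit_solubility(temp_c)
  # vapour pressure of water (atm) and partial molar volume term
  p_wv <- exp(11.8571 - 3840.70 / tk - 216961 / tk^2)
  theta <- 0.000975 - 1.426e-5 * temp_c + 6.436e-8 * temp_c^2
  p <- pressure_atm
  c_star * p * ((1 - p_wv / p) * (1 - theta * p)) / ((1 - p_wv) * (1 - theta))
}

#' Departure of dissolved oxygen from 100% saturation
#'
#' Signed percent departure of a DO concentration from its solubility:
#' `100 * (do_conc - do_sol) / do_sol`. Positive values indicate
#' supersaturation (net biological/biogeochemical oxygen production), negative
#' values undersaturation. Setting `type = "percent"` instead returns percent
#' of saturation (`100 * do_conc / do_sol`).
#'
#' @param do_conc dissolved-oxygen concentration, mg/L.
#' @param do_sol solubility at ambient conditions, mg/L; must be positive.
#' @param type `"departure"` (default) or `"percent"`.
#' @return percent, vectorised.
#' @export
#' @examples
#' do_sp(11, 10)   # +10
#' do_sp(5, 10)    # -50
do_sp <- function(do_conc, do_sol, type = c("departure", "percent")) {
  type <- match.arg(type)
  if (any(do_sol <= 0)) {
    abort("`do_sol` must be positive", class = "lakedo_error_validation")
  }
  if (type == "departure") 100 * (do_conc - do_sol) / do_sol else 100 * do_conc / do_sol
}

#' Augment a DO series with solubility and saturation departure
#'
#' Adds `do_sol` (from `tair`/`pressure`) and `do_sp` columns to a data frame
#' carrying a DO series. Air temperature is clamped to `[0, 40]` degC before the
#' solubility evaluation (frozen or near-boiling surface water is outside the
#' model's domain).
#'
#' @param df data frame with columns `tair` (degC), `pressure` (atm) and the DO
#'   column named by `do_col`.
#' @param do_col name of the DO concentration column (default `"do"`).
#' @return the input as a tibble with `do_sol` and `do_sp` columns appended.
#' @export
add_oxygen_state <- function(df, do_col = "do") {
  check_columns(df, c("tair", "pressure", do_col), "DO series")
  t_clamp <- pmin(pmax(df$tair, 0), 40)
  out <- as_tibble(df)
  out$do_sol <- o2_solubility(t_clamp, df$pressure)
  out$do_sp <- do_sp(out[[do_col]], out$do_sol)
  out
}

#' Seasonal amplitude of a monthly DO cycle
#'
#' Difference between the maximum and minimum monthly mean, the conventional
#' measure of the seasonal DO cycle's size. Months with sub-zero air
#' temperature should be masked (set `NA`) upstream so ice-covered conditions
#' do not enter the cycle.
#'
#' @param df data frame with columns `month` (1-12) and `value` (monthly mean,
#'   mg/L); missing months as `NA` values or absent rows.
#' @return one-row tibble with `delta_do`, `month_max`, `month_min`, `n_valid`
#'   and a logical `defined` flag (`FALSE` when fewer than 2 valid months).
#' @export
#' @examples
#' seasonal_amplitude(data.frame(month = 1:12, value = c(rep(8, 11), 11)))
seasonal_amplitude <- function(df) {
  check_columns(df, c("month", "value"), "monthly means")
  if (any(!df$month %in% 1:12)) {
    abort("`month` must be in 1..12", class = "lakedo_error_validation")
  }
  ok <- !is.na(df$value)
  n_valid <- sum(ok)
  if (n_valid < 2) {
    warn("fewer than 2 valid months: seasonal amplitude undefined")
    return(tibble(delta_do = NA_real_, month_max = NA_integer_,
                  month_min = NA_integer_, n_valid = n_valid, defined = FALSE))
  }
  v <- df$value[ok]; m <- df$month[ok]
  tibble(
    delta_do = max(v) - min(v),
    month_max = m[which.max(v)],
    month_min = m[which.min(v)],
    n_valid = n_valid,
    defined = TRUE
  )
}
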