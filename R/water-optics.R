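# Water-colour features and water-identification filters.
#
# Two features feed the DO model: the floating algae index (FAI), a linear
# NIR-above-baseline height using the red and SWIR bands as the baseline, and
# the CIE chromaticity hue angle, computed from blue/green/red reflectance via
# the tristimulus transform. Both operate on water-leaving reflectance.

# MODIS band-centre wavelengths (nm) fixed by the FAI definition
FAI_RED_NM <- 645
FAI_NIR_NM <- 859
FAI_SWIR_NM <- 1240

#' Floating algae index
#'
#' FAI is the NIR reflectance minus the linear baseline interpolated between
#' the red (645 nm) and SWIR (1240 nm) bands:
#' `r_nir - r_red - (r_swir - r_red) * (859 - 645) / (1240 - 645)`.
#' Elevated FAI indicates dense surface phytoplankton; it is the pipeline's
#' eutrophication proxy.
#'
#' @param df data frame with reflectance columns `r_red`, `r_nir`, `r_swir`
#'   (dimensionless, each >= 0).
#' @return the input as a tibble with a `fai` column appended.
#' @export
#' @examples
#' fai(data.frame(r_red = 0.02, r_nir = 0.05, r_swir = 0.01))
fai <- function(df) {
  check_columns(df, c("r_red", "r_nir", "r_swir"), "reflectance")
  bands <- cbind(df$r_red, df$r_nir, df$r_swir)
  if (any(!is.finite(bands)) || any(bands < 0)) {
    abort("reflectance bands must be finite and non-negative", class = "lakedo_error_validation")
  }
  frac <- (FAI_NIR_NM - FAI_RED_NM) / (FAI_SWIR_NM - FAI_RED_NM)
  out <- as_tibble(df)
  out$fai <- df$r_nir - df$r_red - (df$r_swir - df$r_red) * frac
  out
}

#' Chromaticity hue angle
#'
#' Computes the CIE tristimulus values from blue/green/red water-leaving
#' reflectance, the chromaticity coordinates `(x, y)`, the hue angle `a` around
#' the white point, the degree-5 polynomial hue correction `delta_a`, and the
#' corrected hue angle `a' = a - delta_a`. The hue angle is a compact trophic
#' state indicator: clear blue water sits at high hue angles, turbid green
#' water at low ones.
#'
#' The angle is taken as the two-argument arctangent with numerator
#' `x - white_point` and denominator `y - white_point`, shifted by +180 so
#' `a` lies in `(0, 360]`. Both the argument order and the white point (0.33)
#' are exposed as arguments because published transcriptions differ.
#'
#' @param df data frame with columns `r_blue`, `r_green`, `r_red`.
#' @param white_point chromaticity white point (default 0.33).
#' @return the input as a tibble with columns `cie_x`, `cie_y`, `hue_a`
#'   (uncorrected, degrees), `hue_delta`, `hue_angle` (corrected) and a logical
#'   `hue_undefined` flag (white-point singularity) appended.
#' @export
hue_angle <- function(df, white_point = 0.33) {
  check_columns(df, c("r_blue", "r_green", "r_red"), "reflectance")
  bands <- cbind(df$r_blue, df$r_green, df$r_red)
  if (any(!is.finite(bands)) || any(bands < 0)) {
    abort("reflectance bands must be finite and non-negative", class = "lakedo_error_validation")
  }
  if (any(rowSums(bands) == 0)) {
    abort("all-zero reflectance: tristimulus undefined", class = "lakedo_error_validation")
  }
  X <- 2.7689 * df$r_red + 1.7517 * df$r_green + 1.1302 * df$r_blue
  Y <- 1.0000 * df$r_red + 4.5906 * df$r_green + 0.0601 * df$r_blue
  Z <- 0.0565 * df$r_green + 5.5943 * df$r_blue
  s <- X + Y + Z
  x <- X / s
  y <- Y / s
  undefined <- abs(x - white_point) < 1e-12 & abs(y - white_point) < 1e-12
  a <- atan2(x - white_point, y - white_point) * 180 / pi + 180
  a[undefined] <- NA_real_
  d <- hue_delta(a)
  out <- as_tibble(df)
  out$cie_x <- x
  out$cie_y <- y
  out$hue_a <- a
  out$hue_delta <- d
  out$hue_angle <- a - d
  out$hue_undefined <- undefined
  out
}

#' Hue-angle polynomial correction
#'
#' The degree-5 polynomial in `a/100` that corrects the discrete-band hue
#' angle towards its hyperspectral equivalent.
#'
#' @param a uncorrected hue angle, degrees.
#' @return correction in degrees.
#' @export
#' @examples
#' hue_delta(100)  # 1.2175, the coefficient sum
hue_delta <- function(a) {
  u <- a / 100
  -1.8185 * u^5 - 62.461 * u^4 + 320.49 * u^3 - 510.97 * u^2 + 306.32 * u - 50.343
}

#' Water mask from NDWI with histogram-splitting threshold
#'
#' NDWI = (green - NIR) / (green + NIR); the water/land threshold is chosen by
#' Otsu's histogram-splitting criterion on the NDWI distribution, and pixels at
#' or above the threshold are classed as water. Pixels with `green + NIR = 0`
#' get `NA` NDWI and an `NA` mask entry. When the NDWI histogram is degenerate
#' (all values equal) the threshold is undefined and the whole scene is
#' returned as water with a warning.
#'
#' @param green,nir equal-shaped numeric vectors or matrices of reflectance.
#' @return list of class `lakedo_watermask` with elements `mask` (logical, same
#'   shape as input), `ndwi` and `threshold`.
#' @export
ndwi_mask <- function(green, nir) {
  if (length(green) != length(nir)) {
    abort("`green` and `nir` must have equal length", class = "lakedo_error_alignment")
  }
  denom <- green + nir
  ndwi <- ifelse(denom == 0, NA_real_, (green - nir) / denom)
  valid <- ndwi[!is.na(ndwi)]
  if (length(valid) == 0) {
    abort("no valid pixels for NDWI", class = "lakedo_error_validation")
  }
  if (diff(range(valid)) < 1e-12) {
    warn("degenerate NDWI histogram: threshold undefined, returning all-water mask")
    mask <- !is.na(ndwi)
    mask[is.na(ndwi)] <- NA
    out <- list(mask = restore_shape(mask, green), ndwi = restore_shape(ndwi, green),
                threshold = NA_real_)
    class(out) <- "lakedo_watermask"
    return(out)
  }
  # Otsu on NDWI rescaled from [-1, 1] to [0, 1]
  img <- EBImage::Image((restore_shape(ndwi, green) + 1) / 2)
  img[is.na(img)] <- 0.5
  thr <- EBImage::otsu(img, range = c(0, 1)) * 2 - 1
  mask <- ndwi >= thr
  mask[is.na(ndwi)] <- NA
  out <- list(mask = restore_shape(mask, green), ndwi = restore_shape(ndwi, green),
              threshold = thr)
  class(out) <- "lakedo_watermask"
  out
}

restore_shape <- function(x, template) {
  if (is.matrix(template)) matrix(x, nrow(template), ncol(template)) else x
}

#' Apply optical-depth, occurrence, erosion and component-size filters
#'
#' Post-processes a water mask the way lake pixels are screened before feature
#' extraction: pixels with optical depth (OD) below `od_min` are removed,
#' pixels with water-occurrence frequency at or below `occ_min` percent are
#' removed, the surviving mask is eroded inward by one pixel (4-connectivity,
#' removing mixed shoreline pixels), and 4-connected components with fewer
#' than `min_component` pixels are discarded.
#'
#' @param mask logical matrix (water = `TRUE`).
#' @param od optical-depth matrix aligned with `mask`.
#' @param occurrence water-occurrence percentage matrix aligned with `mask`.
#' @param od_min minimum OD retained (default 20; strictly below is removed).
#' @param occ_min occurrence percentage that must be exceeded (default 70).
#' @param min_component minimum connected-component size retained (default 4).
#' @param erode erode the mask inward by one pixel (default `TRUE`).
#' @return filtered logical matrix.
#' @export
apply_water_filters <- function(mask, od, occurrence, od_min = 20, occ_min = 70,
                                min_component = 4, erode = TRUE) {
  if (!all(dim(mask) == dim(od)) || !all(dim(mask) == dim(occurrence))) {
    abort("`mask`, `od` and `occurrence` must share dimensions", class = "lakedo_error_alignment")
  }
  m <- mask & !is.na(mask) & od >= od_min & occurrence > occ_min
  if (erode && any(m)) {
    kern <- EBImage::makeBrush(3, shape = "diamond")
    m <- EBImage::erode(matrix(as.integer(m), nrow(m), ncol(m)), kern) > 0
  }
  if (any(m)) {
    lab <- EBImage::bwlabel(matrix(as.integer(m), nrow(m), ncol(m)))
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_component)
    m <- matrix(lab %in% keep, nrow(m), ncol(m))
  }
  m
}

#' Spatial-homogeneity screen for a 3x3 pixel window
#'
#' A matchup uses the mean of the 3x3 reflectance window centred on the
#' sampling location, and the window is accepted only if its coefficient of
#' variation (population SD divided by the mean) is strictly below `cv_max`.
#' The nine window pixels are treated as the full population, so the SD uses
#' the 1/9 divisor.
#'
#' @param values numeric vector of the nine window values.
#' @param cv_max CV acceptance bound (default 0.10).
#' @return one-row tibble with `mean`, `cv`, `pass` and `degenerate` (mean = 0)
#'   columns.
#' @export
#' @examples
#' window_cv(rep(0.05, 9))
window_cv <- function(values, cv_max = 0.10) {
  if (length(values) != 9 || any(!is.finite(values))) {
    abort("`values` must be nine finite numbers", class = "lakedo_error_validation")
  }
  m <- mean(values)
  if (m == 0) {
    return(tibble(mean = 0, cv = NA_real_, pass = FALSE, degenerate = TRUE))
  }
  sd_pop <- sqrt(mean((values - m)^2))
  cv <- sd_pop / abs(m)
  tibble(mean = m, cv = cv, pass = cv < cv_max, degenerate = FALSE)
}
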