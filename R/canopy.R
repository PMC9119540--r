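#' Savitzky-Golay smoothing of a gappy time series
#'
#' Least-squares local-polynomial smoothing. Interior points use the
#' symmetric window; the first and last half-windows are fitted with
#' shifted full-length windows, which preserves exactness on polynomials
#' up to `order` everywhere. Gaps (`NA`) are linearly interpolated before
#' filtering (ends extended with the nearest valid value), which is how
#' cloud-gapped vegetation-index series are pre-conditioned.
#'
#' @param series numeric vector, possibly with `NA` gaps.
#' @param window odd window length, `window > order`.
#' @param order polynomial degree.
#' @return smoothed numeric vector of the same length.
#' @export
sg_smooth <- function(series, window = 5, order = 2) {
  window <- as.integer(window); order <- as.integer(order)
  if (window %% 2 != 1) stop("window must be odd")
  if (window <= order) stop("window must exceed the polynomial order")
  n <- length(series)
  ok <- is.finite(series)
  if (!any(ok)) stop("all-gap series cannot be smoothed")
  if (n < window) stop("series shorter than the window")
  x <- series
  if (!all(ok)) {
    idx <- seq_len(n)
    x <- stats::approx(idx[ok], series[ok], xout = idx, rule = 2)$y
  }
  as.numeric(signal::sgolayfilt(x, p = order, n = window))
}

#' Savitzky-Golay convolution weights
#'
#' The interior-point smoothing weights for a given window and order,
#' e.g. `(-3, 12, 17, 12, -3)/35` for window 5, order 2.
#'
#' @inheritParams sg_smooth
#' @return numeric vector of length `window`.
#' @export
sg_weights <- function(window = 5, order = 2) {
  m <- signal::sgolay(p = order, n = window)
  as.numeric(m[(window + 1) / 2, ])
}

#' Linear LAI from NDVI
#'
#' Leaf area index is taken as a linear function of NDVI, clipped at
#' zero. The coefficients are site calibration inputs.
#'
#' @param ndvi NDVI values.
#' @param slope,intercept linear coefficients (m2 m-2 per NDVI unit and
#'   m2 m-2).
#' @return LAI (>= 0), same shape as `ndvi`.
#' @export
ndvi_to_lai <- function(ndvi, slope = 6, intercept = -0.6) {
  stopifnot(is.finite(slope), is.finite(intercept))
  pmax(slope * ndvi + intercept, 0)
}

#' Fractional vegetation cover from LAI
#'
#' Beer's-law gap fraction under the sensor view angle:
#' `fc = 1 - exp(-0.5 * clumping * lai / cos(view_zenith))`, capped at
#' 0.99 so that the soil-temperature inversion from the composite
#' radiometric temperature never divides by zero at full cover.
#'
#' @param lai leaf area index (>= 0).
#' @param view_zenith sensor view zenith angle, radians, in [0, pi/2).
#' @param clumping clumping index (1 = random canopy).
#' @return fractional cover in [0, 0.99].
#' @export
fractional_cover <- function(lai, view_zenith = 0, clumping = 1) {
  if (any(view_zenith >= pi / 2 | view_zenith < 0))
    stop("view zenith must lie in [0, pi/2)")
  stopifnot(all(lai >= 0 | is.na(lai)))
  pmin(1 - exp(-0.5 * clumping * lai / cos(view_zenith)), 0.99)
}

#' Broadband shortwave albedo from band reflectances
#'
#' Narrowband-to-broadband weighted sum with configurable coefficients;
#' the defaults are the standard Landsat TM conversion weights
#' (bands 1, 3, 4, 5, 7 plus offset). Synthetic scenes carry broadband
#' albedo directly and bypass this conversion.
#'
#' @param band_reflectances named list/vector of band reflectances in
#'   [0, 1]; names must cover `names(coefficients)` minus `"offset"`.
#' @param coefficients named numeric vector of weights, with an
#'   `"offset"` element.
#' @return broadband albedo, clipped to [0, 1].
#' @export
broadband_albedo <- function(band_reflectances,
                             coefficients = c(b1 = 0.356, b3 = 0.130,
                                              b4 = 0.373, b5 = 0.085,
                                              b7 = 0.072,
                                              offset = -0.0018)) {
  need <- setdiff(names(coefficients), "offset")
  have <- names(band_reflectances)
  if (!all(need %in% have))
    stop("missing band(s): ", paste(setdiff(need, have), collapse = ", "))
  acc <- coefficients[["offset"]]
  for (b in need) acc <- acc + coefficients[[b]] * band_reflectances[[b]]
  pmin(pmax(acc, 0), 1)
}

#' Clear-sky atmospheric emissivity
#'
#' Brutsaert-type power law `emis_atm = coeff * (ea / Ta)^(1/7)` with the
#' vapour pressure in hPa, clipped to (0, 1].
#'
#' @param Ta air temperature, K (> 150).
#' @param vapour_pressure_hpa water vapour pressure, hPa (>= 0).
#' @param coeff leading coefficient (default 1.24).
#' @return atmospheric emissivity in (0, 1].
#' @export
atmospheric_emissivity <- function(Ta, vapour_pressure_hpa, coeff = 1.24) {
  stopifnot(all(Ta > 150), all(vapour_pressure_hpa >= 0 |
                                 is.na(vapour_pressure_hpa)))
  pmin(pmax(coeff * (vapour_pressure_hpa / Ta)^(1 / 7), 1e-6), 1)
}

#' Blend surface emissivity over vegetation cover
#'
#' @param fc fractional vegetation cover in [0, 1].
#' @param emis_veg,emis_soil endmember emissivities.
#' @return surface emissivity.
#' @export
surface_emissivity <- function(fc, emis_veg = 0.98, emis_soil = 0.95) {
  fc * emis_veg + (1 - fc) * emis_soil
}
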