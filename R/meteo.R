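#' Physical constants and model parameters
#'
#' Returns the default constant set used throughout the energy-balance
#' computations, with any element overridable. Units:
#' \describe{
#'   \item{sigma}{Stefan-Boltzmann constant, W m-2 K-4.}
#'   \item{rho}{air density, kg m-3 (recomputed from pressure and
#'     temperature where both are available).}
#'   \item{Cp}{heat capacity of air at constant pressure, J kg-1 K-1.}
#'   \item{gamma}{psychrometric constant, kPa K-1 (0.066).}
#'   \item{L}{latent heat of vaporization, MJ m-2 per mm of water (2.45).}
#'   \item{cg}{soil heat flux as a fixed fraction of soil net radiation
#'     (0.35).}
#'   \item{k_ext}{extinction coefficient for the radiation partition over
#'     leaf area index.}
#'   \item{alpha_pt_init}{initial Priestley-Taylor coefficient (1.26,
#'     unstressed vegetation).}
#'   \item{alpha_pt_step}{decrement applied to the P-T coefficient per
#'     iteration of the canopy-temperature loop.}
#'   \item{kappa}{von Karman constant.}
#' }
#'
#' @param ... named overrides, e.g. `et_constants(cg = 0.3)`.
#' @return named list of constants.
#' @export
et_constants <- function(...) {
  consts <- list(
    sigma = 5.67e-8,
    rho = 1.2,
    Cp = 1005,
    gamma = 0.066,
    L = 2.45,
    cg = 0.35,
    k_ext = 0.45,
    alpha_pt_init = 1.26,
    alpha_pt_step = 0.1,
    kappa = 0.41,
    # soil aerodynamic resistance 1/(a + b * u_s) and in-canopy wind decay
    ras_a = 0.004,
    ras_b = 0.012,
    z_soil = 0.05,
    # emissivities and green fraction defaults
    emis_veg = 0.98,
    emis_soil = 0.95,
    fg = 1.0,
    # stress-ramp thresholds (cropland defaults) for the gap-filler
    tmin_open = 285.17, tmin_close = 265.15,
    vpd_open = 0.65, vpd_close = 4.3,
    stress_floor = 0.05
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(consts))
    if (length(bad)) stop("unknown constant(s): ", paste(bad, collapse = ", "))
    consts[names(ov)] <- ov
  }
  stopifnot(consts$cg > 0, consts$cg < 1, consts$alpha_pt_init >= 0)
  consts
}

#' Saturation vapour pressure and its slope (Tetens)
#'
#' @param Ta air temperature in K.
#' @return `esat_kpa`: saturation vapour pressure in kPa;
#'   `esat_slope`: slope of the saturation curve, kPa K-1.
#' @export
esat_kpa <- function(Ta) {
  Tc <- Ta - 273.15
  0.6108 * exp(17.27 * Tc / (Tc + 237.3))
}

#' @rdname esat_kpa
#' @export
esat_slope <- function(Ta) {
  Tc <- Ta - 273.15
  4098 * esat_kpa(Ta) / (Tc + 237.3)^2
}

#' Actual vapour pressure from specific humidity
#'
#' @param q specific humidity, kg kg-1.
#' @param P surface pressure, kPa.
#' @return vapour pressure, kPa.
#' @export
vapour_pressure <- function(q, P) q * P / (0.622 + 0.378 * q)

#' Air density from pressure and temperature
#'
#' Ideal-gas density of (moist-ignored) air.
#'
#' @param P pressure, kPa.
#' @param Ta temperature, K.
#' @return density, kg m-3.
#' @export
air_density <- function(P, Ta) 1000 * P / (287.05 * Ta)

forcing_required_cols <- c("date", "ta_k", "tmin_k", "u_ms", "p_kpa",
                           "sd_wm2", "sd24_mj", "theta_sm")

#' Load daily meteorological forcing
#'
#' Reads a forcing table (CSV) with one row per day and returns it with
#' the derived quantities attached. Required columns: `date`, `ta_k`
#' (air temperature at overpass, K), `tmin_k` (daily minimum, K), `u_ms`
#' (wind speed, m s-1), `p_kpa` (pressure, kPa), `sd_wm2` (instantaneous
#' downward shortwave, W m-2), `sd24_mj` (daily shortwave sum,
#' MJ m-2 d-1), `theta_sm` (0-10 cm volumetric soil moisture). Optional:
#' `ta24_k` (daily mean temperature; defaults to `ta_k`), `q_kgkg`
#' (specific humidity), `vpd_kpa` and `vpd24_kpa` (vapour pressure
#' deficits; computed from `q_kgkg` when absent), `sza_rad` (solar zenith
#' at overpass; defaults to 30 degrees).
#'
#' Derived columns: `delta_kpa_k` and `delta24_kpa_k` (saturation-slope at
#' overpass / daily temperature), `ea_kpa` (actual vapour pressure),
#' `vpd_kpa`, `vpd24_kpa`, `rho_kgm3`.
#'
#' @param path CSV file path, or a data.frame already in memory.
#' @return data.frame of daily forcing, one row per day.
#' @export
load_forcing <- function(path) {
  df <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warning("empty forcing table")
    return(df)
  }
  missing_cols <- setdiff(forcing_required_cols, names(df))
  if (length(missing_cols))
    stop("forcing table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) stop("unparseable dates in forcing table")
  if (nrow(df) > 1 && any(diff(as.numeric(df$date)) <= 0))
    stop("forcing timestamps must be strictly increasing")
  if (is.null(df$ta24_k)) df$ta24_k <- df$ta_k
  if (is.null(df$sza_rad)) df$sza_rad <- 30 * pi / 180
  stopifnot(all(df$ta_k > 150), all(df$u_ms >= 0),
            all(df$theta_sm >= 0 & df$theta_sm <= 1))
  df$delta_kpa_k <- esat_slope(df$ta_k)
  df$delta24_kpa_k <- esat_slope(df$ta24_k)
  if (is.null(df$ea_kpa)) {
    if (!is.null(df$q_kgkg)) {
      df$ea_kpa <- vapour_pressure(df$q_kgkg, df$p_kpa)
    } else if (!is.null(df$vpd_kpa)) {
      df$ea_kpa <- pmax(esat_kpa(df$ta_k) - df$vpd_kpa, 0)
    } else {
      stop("forcing needs q_kgkg, vpd_kpa or ea_kpa to fix humidity")
    }
  }
  if (is.null(df$vpd_kpa)) df$vpd_kpa <- pmax(esat_kpa(df$ta_k) - df$ea_kpa, 0)
  if (is.null(df$vpd24_kpa))
    df$vpd24_kpa <- pmax(esat_kpa(df$ta24_k) - df$ea_kpa, 0)
  df$rho_kgm3 <- air_density(df$p_kpa, df$ta_k)
  df
}

#' FAO-56 extraterrestrial and clear-sky daily shortwave radiation
#'
#' @param doy day of year (1-366).
#' @param lat_deg latitude in degrees.
#' @return `extraterrestrial_radiation`: MJ m-2 d-1 at the top of the
#'   atmosphere; `clearsky_radiation`: 0.75 of it, the standard clear-sky
#'   transmissivity used for the longwave cloudiness factor.
#' @export
extraterrestrial_radiation <- function(doy, lat_deg) {
  phi <- lat_deg * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  dec <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  ws <- acos(pmin(pmax(-tan(phi) * tan(dec), -1), 1))
  24 * 60 / pi * 0.0820 * dr *
    (ws * sin(phi) * sin(dec) + cos(phi) * cos(dec) * sin(ws))
}

#' @rdname extraterrestrial_radiation
#' @export
clearsky_radiation <- function(doy, lat_deg) {
  0.75 * extraterrestrial_radiation(doy, lat_deg)
}
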