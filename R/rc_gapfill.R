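#' Invert canopy resistance from latent heat via Penman-Monteith
#'
#' Solves the Penman-Monteith combination equation
#' `LE = [Delta*(Rn - G) + rho*Cp*VPD/ra] / [Delta + gamma*(1 + Rc/ra)]`
#' for the bulk canopy resistance:
#' `Rc = ra * ([Delta*(Rn-G) + rho*Cp*VPD/ra] / (gamma*LE)
#'             - Delta/gamma - 1)`.
#' Negative solutions (LE above the `Rc = 0` bound) are floored at
#' `rc_min` and flagged via the `floored` attribute.
#'
#' @param LE latent heat flux, W m-2 (> 0; non-positive values return
#'   `NA`).
#' @param Rn,G net radiation and soil heat flux, W m-2.
#' @param Delta saturation-slope, kPa K-1.
#' @param VPD vapour pressure deficit, kPa.
#' @param ra aerodynamic resistance, s m-1 (> 0).
#' @param consts constants from [et_constants()].
#' @param rho air density, kg m-3.
#' @param rc_min floor for the returned resistance, s m-1.
#' @return canopy resistance, s m-1, with attribute `floored` (logical).
#' @export
invert_canopy_resistance <- function(LE, Rn, G, Delta, VPD, ra,
                                     consts = et_constants(),
                                     rho = consts$rho, rc_min = 0) {
  stopifnot(all(ra > 0))
  num <- Delta * (Rn - G) + rho * consts$Cp * VPD / ra
  rc <- ra * (num / (consts$gamma * LE) - Delta / consts$gamma - 1)
  bad <- !is.finite(LE) | LE <= 0
  rc[bad] <- NA_real_
  floored <- !bad & rc < rc_min
  rc[floored] <- rc_min
  attr(rc, "floored") <- floored
  rc
}

#' Forward Penman-Monteith latent heat flux
#'
#' @inheritParams invert_canopy_resistance
#' @param Rc canopy resistance, s m-1 (>= 0).
#' @param floor_zero floor the result at zero (default `TRUE`; the
#'   unfloored value is what [invert_canopy_resistance()] round-trips).
#' @return latent heat flux, W m-2.
#' @export
pm_latent_heat <- function(Rc, Delta, Rn, G, VPD, ra,
                           consts = et_constants(), rho = consts$rho,
                           floor_zero = TRUE) {
  stopifnot(all(Rc >= 0, na.rm = TRUE), all(ra > 0))
  le <- (Delta * (Rn - G) + rho * consts$Cp * VPD / ra) /
    (Delta + consts$gamma * (1 + Rc / ra))
  if (floor_zero) pmax(le, 0) else le
}

#' Temperature and humidity stress scalars
#'
#' Linear ramps limiting potential stomatal conductance: full opening
#' (`m = 1`) for daily minimum temperature at or above `tmin_open` and
#' closure toward the floor at or below `tmin_close`; full opening for
#' VPD at or below `vpd_open` and closure at or above `vpd_close`.
#' Defaults are the cropland parameterization of the MOD16-style
#' restriction functions. Floors keep the scalars strictly positive so
#' the reconstructed resistance stays finite.
#'
#' @param Tmin daily minimum air temperature, K.
#' @param VPD daily vapour pressure deficit, kPa.
#' @param consts constants from [et_constants()] carrying `tmin_open`,
#'   `tmin_close`, `vpd_open`, `vpd_close`, `stress_floor`.
#' @return list with `m_tmin` and `m_vpd`, each in `[floor, 1]`.
#' @export
stress_scalars <- function(Tmin, VPD, consts = et_constants()) {
  if (consts$tmin_open <= consts$tmin_close ||
      consts$vpd_close <= consts$vpd_open)
    stop("stress thresholds must be ordered (close < open ramps)")
  fl <- consts$stress_floor
  ramp_up <- (Tmin - consts$tmin_close) /
    (consts$tmin_open - consts$tmin_close)
  m_tmin <- fl + (1 - fl) * pmin(pmax(ramp_up, 0), 1)
  ramp_dn <- (consts$vpd_close - VPD) / (consts$vpd_close - consts$vpd_open)
  m_vpd <- fl + (1 - fl) * pmin(pmax(ramp_dn, 0), 1)
  list(m_tmin = m_tmin, m_vpd = m_vpd)
}

#' Reconstruct cloudy-day canopy resistance from a clear day
#'
#' `Rc_unc = (LAI_clr * Rc_clr) / (LAI_unc * m_tmin * m_vpd)`:
#' the clear-day resistance is rescaled by the leaf-area ratio and
#' increased under temperature/humidity stress.
#'
#' @param Rc_clr clear-day canopy resistance, s m-1.
#' @param lai_clr,lai_unc leaf area index on the clear and cloudy day.
#' @param m_tmin,m_vpd stress scalars from [stress_scalars()] (> 0).
#' @return cloudy-day canopy resistance, s m-1; `NA` where
#'   `lai_unc <= 0`.
#' @export
reconstruct_resistance <- function(Rc_clr, lai_clr, lai_unc,
                                   m_tmin = 1, m_vpd = 1) {
  stopifnot(all(m_tmin > 0), all(m_vpd > 0))
  out <- (lai_clr * Rc_clr) / (lai_unc * m_tmin * m_vpd)
  out[lai_unc <= 0] <- NA_real_
  out
}

#' Fill cloudy days of a daily ET series by canopy-resistance scaling
#'
#' For every cloudy pixel-date within `max_gap` days of a clear date:
#' pick the nearest clear date (earlier date on ties), invert that
#' day's canopy resistance from its daily ET through Penman-Monteith
#' (daily-mean meteorology, daily available energy converted to W m-2),
#' rescale it to the cloudy day with the daily leaf area index and the
#' day's stress scalars, run Penman-Monteith forward, and convert to
#' mm d-1. Gaps longer than `max_gap` stay `NA`.
#'
#' @param et24 matrix days x pixels of clear-day daily ET (mm d-1) with
#'   `NA` on cloudy days.
#' @param clear logical vector per day: clear scene available.
#' @param lai matrix days x pixels of daily leaf area index.
#' @param rn24 matrix days x pixels (or vector per day) of daily net
#'   radiation, MJ m-2 d-1.
#' @param forcing daily forcing data.frame from [load_forcing()] (uses
#'   `delta24_kpa_k`, `vpd24_kpa`, `tmin_k`, `u_ms`, `rho_kgm3`).
#' @param ra matrix days x pixels (or vector per day) of aerodynamic
#'   resistance for the Penman-Monteith step, s m-1.
#' @param max_gap maximum reconstruction distance in days (default 5).
#' @param consts constants from [et_constants()].
#' @return list: `et24` filled matrix; `source_day` integer matrix of the
#'   clear day index each cloudy value was reconstructed from (`NA` for
#'   clear days and unfilled gaps); `rc` matrix of the canopy
#'   resistances used (clear-day inversions and reconstructions);
#'   `flag` character matrix "clear" / "reconstructed" / "gap".
#' @export
fill_season <- function(et24, clear, lai, rn24, forcing, ra, max_gap = 5,
                        consts = et_constants()) {
  nd <- nrow(et24); np <- ncol(et24)
  stopifnot(length(clear) == nd, nrow(lai) == nd)
  as_mat <- function(x) if (is.matrix(x)) x else matrix(x, nd, np)
  rn24 <- as_mat(rn24); ra <- as_mat(ra)
  clear_idx <- which(clear)
  if (length(clear_idx) == 0) stop("no clear day available to fill from")

  out <- et24
  src <- matrix(NA_integer_, nd, np)
  rc_used <- matrix(NA_real_, nd, np)
  flag <- matrix(ifelse(clear, "clear", "gap"), nd, np)

  stress <- stress_scalars(forcing$tmin_k, forcing$vpd24_kpa, consts)

  # clear-day resistance inversions, one vectorised pass per clear day
  rc_clr <- matrix(NA_real_, nd, np)
  for (d in clear_idx) {
    le_w <- mj_day_to_wm2(et24[d, ] * consts$L)
    avail_w <- mj_day_to_wm2(rn24[d, ])
    rc_clr[d, ] <- invert_canopy_resistance(
      le_w, avail_w, 0, forcing$delta24_kpa_k[d], forcing$vpd24_kpa[d],
      ra[d, ], consts, rho = forcing$rho_kgm3[d])
    rc_used[d, ] <- rc_clr[d, ]
  }

  for (d in which(!clear)) {
    gap <- abs(clear_idx - d)
    if (min(gap) > max_gap) next
    d0 <- clear_idx[which.min(gap)]  # which.min takes the earlier tie
    le <- pm_latent_heat(
      Rc = pmax(reconstruct_resistance(rc_clr[d0, ], lai[d0, ], lai[d, ],
                                       stress$m_tmin[d], stress$m_vpd[d]),
                0),
      Delta = forcing$delta24_kpa_k[d],
      Rn = mj_day_to_wm2(rn24[d, ]), G = 0,
      VPD = forcing$vpd24_kpa[d], ra = ra[d, ],
      consts = consts, rho = forcing$rho_kgm3[d])
    filled <- wm2_to_mj_day(le) / consts$L
    bad <- !is.finite(filled)
    filled[bad] <- NA_real_
    out[d, ] <- filled
    src[d, !bad] <- d0
    rc_used[d, ] <- reconstruct_resistance(rc_clr[d0, ], lai[d0, ],
                                           lai[d, ], stress$m_tmin[d],
                                           stress$m_vpd[d])
    flag[d, ] <- ifelse(bad, "gap", "reconstructed")
  }
  list(et24 = out, source_day = src, rc = rc_used, flag = flag)
}
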