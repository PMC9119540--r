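#' Daily net radiation from the daily shortwave sum
#'
#' `Rn24 = (1 - albedo) * Sd24 + Lnet24`. The daily net longwave term
#' follows the standard FAO-56 parameterization
#' `Lnet24 = -sigma_d * Ta^4 * (0.34 - 0.14 * sqrt(ea)) *
#'  (1.35 * Sd24/Rso - 0.35)` with `sigma_d = 4.903e-9 MJ K-4 m-2 d-1`
#' and `Rso` the clear-sky daily shortwave; it can be disabled
#' (`longwave = FALSE`) or replaced by a user function.
#'
#' @param Sd24 daily downward shortwave sum, MJ m-2 d-1 (>= 0).
#' @param albedo broadband albedo.
#' @param Ta_mean daily mean air temperature, K.
#' @param ea actual vapour pressure, kPa.
#' @param Rso clear-sky daily shortwave, MJ m-2 d-1 (see
#'   [clearsky_radiation()]).
#' @param longwave logical; include the net longwave term.
#' @return daily net radiation, MJ m-2 d-1.
#' @export
daily_net_radiation <- function(Sd24, albedo, Ta_mean = NULL, ea = NULL,
                                Rso = NULL, longwave = TRUE) {
  stopifnot(all(Sd24 >= 0))
  rns <- (1 - albedo) * Sd24
  if (!longwave) return(rns)
  stopifnot(!is.null(Ta_mean), !is.null(ea), !is.null(Rso))
  cf <- pmin(pmax(1.35 * Sd24 / pmax(Rso, 1e-6) - 0.35, 0.05), 1)
  lnet <- -4.903e-9 * Ta_mean^4 * (0.34 - 0.14 * sqrt(pmax(ea, 0))) * cf
  rns + lnet
}

#' Daily ET by the evaporative-fraction method
#'
#' The evaporative fraction `EF = LE / (Rn - G)` at the satellite
#' overpass is assumed constant over the daytime, so
#' `LE24 = (Rn24 - G24) * EF` with the daily mean soil heat flux
#' `G24 = 0`, and `ET24 = LE24 / L` in mm d-1 (clipped at zero).
#' The stored `EF` is the raw computed value; values outside `[0, 1.1]`
#' are flagged as suspect rather than modified.
#'
#' @param LE instantaneous latent heat flux, W m-2.
#' @param Rn instantaneous net radiation, W m-2.
#' @param G instantaneous soil heat flux, W m-2.
#' @param Rn24 daily net radiation, MJ m-2 d-1.
#' @param consts constants from [et_constants()] (`L`).
#' @param G24 daily mean soil heat flux, MJ m-2 d-1 (0 by assumption;
#'   exposed for sensitivity studies only).
#' @return object of class `daily_et`: list of vectors `EF`, `Rn24`,
#'   `G24`, `LE24` (MJ m-2 d-1), `ET24` (mm d-1), `suspect` (logical).
#'   Pixels with `Rn - G == 0` become `NA` with `suspect` set.
#' @export
ef_daily_et <- function(LE, Rn, G, Rn24, consts = et_constants(), G24 = 0) {
  avail <- Rn - G
  EF <- ifelse(avail != 0, LE / avail, NA_real_)
  LE24 <- (Rn24 - G24) * EF
  ET24 <- pmax(LE24 / consts$L, 0)
  structure(list(
    EF = EF, Rn24 = Rn24, G24 = rep_len(G24, length(EF)), LE24 = LE24,
    ET24 = ET24,
    suspect = is.na(EF) | EF < 0 | EF > 1.1
  ), class = "daily_et")
}

#' @export
print.daily_et <- function(x, ...) {
  cat(sprintf("daily_et: %d pixel(s); mean ET24 %.2f mm d-1; %d suspect EF\n",
              length(x$ET24), mean(x$ET24, na.rm = TRUE), sum(x$suspect)))
  invisible(x)
}

# W m-2 daily mean <-> MJ m-2 d-1
wm2_to_mj_day <- function(x) x * 86400 / 1e6
mj_day_to_wm2 <- function(x) x * 1e6 / 86400
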