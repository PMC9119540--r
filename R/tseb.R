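#' Surface net radiation
#'
#' Radiation budget of the composite surface:
#' `Rn = (1 - albedo) * Sd + emis_atm * sigma * Ta^4
#'      - emis_surf * sigma * Trad^4`.
#'
#' @param albedo broadband shortwave albedo.
#' @param Sd downwelling shortwave radiation, W m-2.
#' @param emis_atm,emis_surf atmospheric and surface emissivity.
#' @param Ta air temperature, K.
#' @param Trad surface radiometric temperature, K.
#' @param consts constants from [et_constants()].
#' @return net radiation, W m-2.
#' @export
net_radiation <- function(albedo, Sd, emis_atm, emis_surf, Ta, Trad,
                          consts = et_constants()) {
  (1 - albedo) * Sd + emis_atm * consts$sigma * Ta^4 -
    emis_surf * consts$sigma * Trad^4
}

#' Partition net radiation between canopy and soil
#'
#' Beer's-law interception over leaf area index at the solar zenith
#' angle: `Rnc = Rn * (1 - exp(-k * lai / (2 * cos(sza))))`,
#' `Rns = Rn - Rnc` (conserved by construction).
#'
#' @param Rn total net radiation, W m-2.
#' @param lai leaf area index (>= 0).
#' @param solar_zenith solar zenith angle, radians, in [0, pi/2);
#'   night-time is handled upstream.
#' @param k_ext extinction coefficient.
#' @return list with `Rnc` and `Rns` (W m-2).
#' @export
partition_net_radiation <- function(Rn, lai, solar_zenith,
                                    k_ext = et_constants()$k_ext) {
  if (any(solar_zenith >= pi / 2 | solar_zenith < 0))
    stop("solar zenith must lie in [0, pi/2)")
  Rnc <- Rn * (1 - exp(-k_ext * lai / (2 * cos(solar_zenith))))
  list(Rnc = Rnc, Rns = Rn - Rnc)
}

#' Soil heat flux as a fixed fraction of soil net radiation
#'
#' @param Rns soil net radiation, W m-2.
#' @param cg fixed ratio (default 0.35).
#' @return G, W m-2.
#' @export
soil_heat_flux <- function(Rns, cg = et_constants()$cg) cg * Rns

#' Aerodynamic resistances of the canopy and soil paths
#'
#' Canopy-to-reference-height resistance from the neutral logarithmic
#' wind profile with displacement height `0.65 h` and roughness length
#' `0.125 h`; soil-surface resistance `1/(a + b * u_s)` where `u_s` is
#' the wind speed attenuated to just above the soil by exponential
#' in-canopy decay with attenuation coefficient `0.45 * lai^(2/3)`.
#' No atmospheric-stability correction is applied (neutral profile).
#'
#' @param u wind speed at the reference height, m s-1 (> 0).
#' @param z_ref reference (measurement) height, m.
#' @param canopy_height canopy height, m (0 < h < z_ref).
#' @param lai leaf area index.
#' @param consts constants from [et_constants()].
#' @return list with `ra_c` and `ra_s` (s m-1), both finite positive.
#' @export
aerodynamic_resistances <- function(u, z_ref, canopy_height, lai,
                                    consts = et_constants()) {
  if (any(u <= 0)) stop("wind speed must be positive (calm periods are
filtered upstream)")
  stopifnot(all(z_ref > canopy_height), all(canopy_height > 0))
  d <- 0.65 * canopy_height
  z0m <- 0.125 * canopy_height
  ra_c <- log((z_ref - d) / z0m)^2 / (consts$kappa^2 * u)
  u_h <- u * log((canopy_height - d) / z0m) / log((z_ref - d) / z0m)
  att <- 0.45 * lai^(2 / 3)
  rel <- 1 - pmin(consts$z_soil / canopy_height, 1)
  u_s <- u_h * exp(-att * rel)
  ra_s <- 1 / (consts$ras_a + consts$ras_b * u_s)
  list(ra_c = ra_c, ra_s = ra_s)
}

#' Priestley-Taylor initial canopy temperature
#'
#' `Tc = Ta + (Rnc * ra_c / (rho * Cp)) *
#'       (1 - alpha_pt * fg * Delta / (Delta + gamma))`
#'
#' @param Ta air temperature, K.
#' @param Rnc canopy net radiation, W m-2.
#' @param ra_c canopy aerodynamic resistance, s m-1 (> 0).
#' @param alpha_pt Priestley-Taylor coefficient.
#' @param fg green-vegetation fraction.
#' @param Delta slope of the saturation vapour pressure curve, kPa K-1.
#' @param consts constants from [et_constants()]; `rho` may be overridden
#'   per call through `rho`.
#' @param rho air density, kg m-3 (default from `consts`).
#' @return canopy temperature, K.
#' @export
initial_canopy_temperature <- function(Ta, Rnc, ra_c, alpha_pt, fg, Delta,
                                       consts = et_constants(),
                                       rho = consts$rho) {
  stopifnot(all(ra_c > 0), all(Delta > 0))
  Ta + (Rnc * ra_c / (rho * consts$Cp)) *
    (1 - alpha_pt * fg * Delta / (Delta + consts$gamma))
}

#' Soil temperature from the composite radiometric temperature
#'
#' Inverts `Trad^4 = fc * Tc^4 + (1 - fc) * Ts^4` for the soil
#' temperature. A non-positive radicand means the assumed canopy
#' temperature is too high for the observed composite; that case returns
#' `NA`, which the caller treats as a signal to continue the
#' Priestley-Taylor iteration, not as an error.
#'
#' @param Trad composite radiometric temperature, K.
#' @param Tc canopy temperature, K.
#' @param fc fractional cover in [0, 0.99].
#' @return soil temperature, K, or `NA` where the radicand is
#'   non-positive.
#' @export
soil_temperature_from_composite <- function(Trad, Tc, fc) {
  stopifnot(all(fc >= 0 & fc <= 0.99))
  rad <- (Trad^4 - fc * Tc^4) / (1 - fc)
  ifelse(rad > 0, rad^0.25, NA_real_)
}

#' Solve the two-source energy balance for pixels
#'
#' Vectorised per-pixel solution. Starting from the unstressed
#' Priestley-Taylor coefficient, each iteration computes the canopy
#' temperature, inverts the composite radiometric temperature for the
#' soil temperature, forms the sensible heat fluxes through the series
#' resistance network (`Hc = rho*Cp*(Tc - Ta)/ra_c`,
#' `Hs = rho*Cp*(Ts - Ta)/(ra_c + ra_s)`) and closes the canopy and soil
#' budgets (`LEc = Rnc - Hc`, `LEs = Rns - G - Hs`). If soil evaporation
#' is negative (or the soil-temperature inversion is infeasible) the
#' coefficient is decremented and the pixel re-solved; pixels still
#' unsolved at the floor take the standard completion `LEs = 0`,
#' `Hs = Rns - G`, with `Ts` recovered from `Hs`, `Tc` from the
#' composite, and `LEc = Rnc - Hc` floored at zero with the residual
#' returned to `Hc` (fallback flag set). All energy budgets close
#' exactly at return on every path.
#'
#' @param Trad composite radiometric temperature, K.
#' @param Ta air temperature, K.
#' @param Delta saturation-slope at `Ta`, kPa K-1.
#' @param lai leaf area index.
#' @param fc fractional cover in [0, 0.99].
#' @param fg green-vegetation fraction.
#' @param albedo broadband albedo.
#' @param emis_surf,emis_atm surface and atmospheric emissivity.
#' @param Sd downwelling shortwave, W m-2.
#' @param solar_zenith solar zenith angle, radians.
#' @param ra_c,ra_s aerodynamic resistances, s m-1.
#' @param consts constants from [et_constants()].
#' @param rho air density, kg m-3.
#' @return object of class `flux_components`: list of equal-length
#'   vectors `Rn, Rnc, Rns, G, Hc, Hs, H, LEc, LEs, LE, Tc, Ts,
#'   alpha_pt_final, iterations, fallback`.
#' @export
tseb_solve <- function(Trad, Ta, Delta, lai, fc, fg = 1, albedo,
                       emis_surf, emis_atm, Sd, solar_zenith,
                       ra_c, ra_s, consts = et_constants(),
                       rho = consts$rho) {
  n <- length(Trad)
  args <- list(Trad, Ta, Delta, lai, fc, fg, albedo, emis_surf, emis_atm,
               Sd, solar_zenith, ra_c, ra_s, rho)
  args <- lapply(args, rep_len, n)
  names(args) <- c("Trad", "Ta", "Delta", "lai", "fc", "fg", "albedo",
                   "emis_surf", "emis_atm", "Sd", "sza", "ra_c", "ra_s",
                   "rho")
  with(args, {
    if (any(!is.finite(Trad) | !is.finite(Ta) | !is.finite(lai)))
      stop("non-finite inputs to the energy-balance solver")
    if (any(fc >= 1)) stop("fractional cover must be below 1")
    Rn <- net_radiation(albedo, Sd, emis_atm, emis_surf, Ta, Trad, consts)
    part <- partition_net_radiation(Rn, lai, sza, consts$k_ext)
    Rnc <- part$Rnc
    Rns <- part$Rns
    G <- soil_heat_flux(Rns, consts$cg)
    rhoCp <- rho * consts$Cp
    ras_tot <- ra_c + ra_s

    alphas <- seq(consts$alpha_pt_init, 0, by = -consts$alpha_pt_step)
    if (alphas[length(alphas)] > 0) alphas <- c(alphas, 0)

    Tc <- Ts <- Hc <- Hs <- rep(NA_real_, n)
    alpha_fin <- rep(NA_real_, n)
    iterations <- integer(n)
    open <- rep(TRUE, n)
    for (it in seq_along(alphas)) {
      if (!any(open)) break
      a <- alphas[it]
      i <- which(open)
      Tci <- initial_canopy_temperature(Ta[i], Rnc[i], ra_c[i], a, fg[i],
                                        Delta[i], consts, rho[i])
      Tsi <- soil_temperature_from_composite(Trad[i], Tci, fc[i])
      Hsi <- rhoCp[i] * (Tsi - Ta[i]) / ras_tot[i]
      LEsi <- Rns[i] - G[i] - Hsi
      ok <- !is.na(Tsi) & LEsi >= 0
      j <- i[ok]
      Tc[j] <- Tci[ok]; Ts[j] <- Tsi[ok]
      Hs[j] <- Hsi[ok]
      Hc[j] <- rhoCp[j] * (Tc[j] - Ta[j]) / ra_c[j]
      alpha_fin[j] <- a
      iterations[j] <- it
      open[j] <- FALSE
    }

    fallback <- open
    if (any(open)) {
      i <- which(open)
      Hs[i] <- Rns[i] - G[i]
      Ts[i] <- Ta[i] + Hs[i] * ras_tot[i] / rhoCp[i]
      radc <- (Trad[i]^4 - (1 - fc[i]) * Ts[i]^4) / fc[i]
      Tc[i] <- ifelse(fc[i] > 0 & radc > 0, abs(radc)^0.25, Trad[i])
      Hc[i] <- rhoCp[i] * (Tc[i] - Ta[i]) / ra_c[i]
      alpha_fin[i] <- 0
      iterations[i] <- length(alphas)
    }

    LEc <- Rnc - Hc
    LEs <- Rns - G - Hs
    if (any(fallback)) {
      i <- which(fallback)
      LEs[i] <- 0
      neg <- i[LEc[i] < 0]
      LEc[neg] <- 0
      Hc[neg] <- Rnc[neg]
    }
    structure(list(
      Rn = Rn, Rnc = Rnc, Rns = Rns, G = G,
      Hc = Hc, Hs = Hs, H = Hc + Hs,
      LEc = LEc, LEs = LEs, LE = LEc + LEs,
      Tc = Tc, Ts = Ts,
      alpha_pt_final = alpha_fin, iterations = iterations,
      fallback = fallback
    ), class = "flux_components")
  })
}

#' @export
print.flux_components <- function(x, ...) {
  n <- length(x$Rn)
  cat(sprintf("flux_components: %d pixel(s)\n", n))
  cat(sprintf("  mean Rn %.1f, G %.1f, H %.1f, LE %.1f W m-2\n",
              mean(x$Rn), mean(x$G), mean(x$H), mean(x$LE)))
  cat(sprintf("  fallback pixels: %d; mean alpha_pt at convergence: %.2f\n",
              sum(x$fallback), mean(x$alpha_pt_final)))
  invisible(x)
}
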