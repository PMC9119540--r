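#' Synthetic season configuration
#'
#' Describes a seeded synthetic wheat/maize rotation season: grid, crop
#' phenology, cloud model, noise levels and meteorology. Defaults
#' emulate a North China Plain cropland year starting 1 October:
#' winter wheat greens up in spring and is harvested by end of May,
#' summer maize grows June-September. Scene truth is built through the
#' package's own forward energy-balance relations, so pipeline tests
#' measure recovery of known truth rather than physical realism.
#'
#' @param seed integer RNG seed; every stochastic element derives from
#'   it.
#' @param nrow,ncol fine grid dimensions (must be divisible by
#'   `coarse_factor`).
#' @param px fine pixel size, m.
#' @param coarse_factor coarse-to-fine resolution ratio (block size).
#' @param start first date of the season (default 1 October 2008).
#' @param n_days season length in days.
#' @param lat_deg site latitude, degrees north.
#' @param fine_revisit fine scenes are available every this many days
#'   (on clear days); 1 means daily.
#' @param cloud_prob probability that a new cloud gap starts on a given
#'   day.
#' @param max_cloud_len maximum gap length, days.
#' @param ndvi_sigma,lst_sigma_k Gaussian observation noise added to the
#'   synthetic NDVI and LST scenes (NDVI units / K).
#' @param met_noise_k day-to-day AR(1) temperature noise amplitude, K.
#' @param lai_slope,lai_intercept linear LAI-NDVI coefficients used by
#'   both generator and pipeline.
#' @param z_ref meteorological reference height, m.
#' @param p_kpa surface pressure, kPa.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(seed = 1, nrow = 60, ncol = 60, px = 30,
                         coarse_factor = 6, start = as.Date("2008-10-01"),
                         n_days = 365, lat_deg = 36.5, fine_revisit = 1,
                         cloud_prob = 0, max_cloud_len = 5,
                         ndvi_sigma = 0, lst_sigma_k = 0,
                         met_noise_k = 1, lai_slope = 6,
                         lai_intercept = -0.6, z_ref = 10, p_kpa = 100) {
  if (nrow %% coarse_factor != 0 || ncol %% coarse_factor != 0)
    stop("coarse_factor must divide the grid dimensions")
  stopifnot(ndvi_sigma >= 0, lst_sigma_k >= 0, max_cloud_len >= 1,
            cloud_prob >= 0, cloud_prob <= 1)
  structure(as.list(environment()), class = "synth_config")
}

#' Canopy height from leaf area index
#'
#' Simple allometric stand height used for the aerodynamic resistances;
#' shared by the generator and the pipeline so both see the same
#' roughness.
#'
#' @param lai leaf area index.
#' @return canopy height, m (>= 0.05).
#' @export
canopy_height_from_lai <- function(lai) pmax(0.05, 0.2 * lai)

#' Broadband albedo from NDVI
#'
#' Linear darkening of cropland albedo with greenness, used when no
#' band reflectances are carried (synthetic scenes and the reduced
#' pipeline): `albedo = 0.25 - 0.10 * ndvi`, clipped to [0.14, 0.25].
#'
#' @param ndvi NDVI values.
#' @return broadband albedo.
#' @export
albedo_from_ndvi <- function(ndvi) pmin(pmax(0.25 - 0.10 * ndvi, 0.14), 0.25)

double_logistic <- function(t, t_on, r_on, t_off, r_off) {
  1 / (1 + exp(-r_on * (t - t_on))) - 1 / (1 + exp(-r_off * (t - t_off)))
}

# NDVI trajectory of the wheat/maize rotation, t = days since 1 October
rotation_ndvi <- function(t, amp) {
  wheat_autumn <- 0.35 * double_logistic(t, 20, 0.25, 85, 0.15)
  wheat_spring <- double_logistic(t, 160, 0.12, 237, 0.25)
  maize <- double_logistic(t, 265, 0.18, 352, 0.30)
  pmin(0.12 + amp * (wheat_autumn + wheat_spring + maize), 0.92)
}

ar1_series <- function(n, phi = 0.8, sd = 1) {
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  for (i in seq_len(n - 1))
    x[i + 1] <- phi * x[i] + stats::rnorm(1, 0, sd * sqrt(1 - phi^2))
  x
}

#' Generate a synthetic season
#'
#' Builds, per date: fine NDVI/LST scenes (double-logistic rotation
#' phenology plus optional noise), coarse scenes by block-mean
#' degradation, daily forcing, and truth fluxes/ET. Canopy temperature
#' truth follows the unstressed Priestley-Taylor relation; soil
#' temperature truth follows a prescribed soil-wetness field through the
#' soil energy budget; the radiometric temperature is composited from
#' both and the radiation budget is iterated to its fixed point, so the
#' energy-balance solver recovers the truth exactly on clear days.
#' Cloud gaps remove both fine and coarse scenes; truth ET on gapped
#' days is constructed by the canopy-resistance reconstruction path
#' anchored to the nearest clear day, i.e. the gap-filling relations
#' hold exactly in truth.
#'
#' @param cfg a [synth_config()].
#' @return object of class `synth_season`: list with `cfg`, `dates`,
#'   `clear` (logical per day), `forcing` (daily data.frame), `grid`
#'   (fine grid spec), `scenes` (per-day fine/coarse NDVI and LST
#'   matrices, `NULL` when unavailable), and `truth` (matrices
#'   days x pixels: `ndvi`, `lai`, `trad`, `rn`, `g`, `le`, `et24`,
#'   plus `rn24` and `ra_c` and the per-day `flag`).
#' @export
generate_season <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  nd <- cfg$n_days
  np <- cfg$nrow * cfg$ncol
  dates <- cfg$start + 0:(nd - 1)
  doy <- as.integer(format(dates, "%j"))
  tsn <- as.numeric(dates - cfg$start)  # days since season start

  # --- cloud gaps (scene level); day 1 forced clear so every gap has an
  #     anchor within max_cloud_len days
  clear <- rep(TRUE, nd)
  d <- 2
  while (d <= nd) {
    if (stats::runif(1) < cfg$cloud_prob) {
      len <- sample.int(cfg$max_cloud_len, 1)
      clear[d:min(nd, d + len - 1)] <- FALSE
      d <- d + len + 1  # at least one clear day between gaps
    } else d <- d + 1
  }

  # --- daily meteorology
  ta24 <- 287.5 + 13 * sin(2 * pi * (doy - 105) / 365) +
    ar1_series(nd, 0.8, cfg$met_noise_k)
  ta24 <- ta24 - ifelse(clear, 0, 1.5)
  tmin <- ta24 - 6 + ar1_series(nd, 0.5, 0.5)
  ta <- ta24 + ifelse(clear, 4, 2)
  rso <- clearsky_radiation(doy, cfg$lat_deg)
  sd24 <- rso * ifelse(clear, 0.97, 0.40) *
    pmin(pmax(1 + 0.03 * ar1_series(nd, 0.5, 1), 0.85), 1.0)
  sd_inst <- mj_day_to_wm2(sd24) * 2.2
  rh <- pmin(pmax(0.55 + 0.15 * sin(2 * pi * (doy - 180) / 365) +
                    0.05 * ar1_series(nd, 0.6, 1), 0.25), 0.95)
  ea <- rh * esat_kpa(ta24)
  q <- 0.622 * ea / (cfg$p_kpa - 0.378 * ea)
  theta <- pmin(pmax(0.24 + 0.06 * sin(2 * pi * (doy - 180) / 365) +
                       0.03 * ar1_series(nd, 0.9, 1), 0.11), 0.38)
  u <- pmin(pmax(2.5 + 0.8 * ar1_series(nd, 0.6, 1), 0.8), 6)
  decl <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  sza <- abs(cfg$lat_deg * pi / 180 - decl)

  forcing <- load_forcing(data.frame(
    date = dates, ta_k = ta, ta24_k = ta24, tmin_k = tmin, u_ms = u,
    p_kpa = cfg$p_kpa, q_kgkg = q, sd_wm2 = sd_inst, sd24_mj = sd24,
    theta_sm = theta, sza_rad = sza))
  forcing$rso_mj <- rso

  # --- truth NDVI / LAI fields
  amp <- matrix(stats::runif(np, 0.45, 0.72), cfg$nrow, cfg$ncol)
  wet_jit <- matrix(stats::runif(np, 0.85, 1.15), cfg$nrow, cfg$ncol)
  ndvi_t <- outer(tsn, as.numeric(amp), rotation_ndvi)  # days x pixels
  lai_t <- ndvi_to_lai(ndvi_t, cfg$lai_slope, cfg$lai_intercept)

  consts <- et_constants()
  trad_t <- rn_t <- g_t <- le_t <- matrix(NA_real_, nd, np)
  et24_t <- matrix(NA_real_, nd, np)
  rn24_t <- matrix(NA_real_, nd, np)
  ra_c_t <- matrix(NA_real_, nd, np)

  for (d in seq_len(nd)) {
    lai <- lai_t[d, ]
    ndvi <- ndvi_t[d, ]
    albedo <- albedo_from_ndvi(ndvi)
    fc <- fractional_cover(lai)
    h <- canopy_height_from_lai(lai)
    res <- aerodynamic_resistances(forcing$u_ms[d], cfg$z_ref, h, lai,
                                   consts)
    ra_c_t[d, ] <- res$ra_c
    rn24_t[d, ] <- daily_net_radiation(forcing$sd24_mj[d], albedo,
                                       forcing$ta24_k[d], forcing$ea_kpa[d],
                                       forcing$rso_mj[d])
    if (!clear[d]) next

    emis_s <- surface_emissivity(fc, consts$emis_veg, consts$emis_soil)
    emis_a <- atmospheric_emissivity(forcing$ta_k[d],
                                     forcing$ea_kpa[d] * 10)
    rho <- forcing$rho_kgm3[d]
    rhoCp <- rho * consts$Cp
    Ta <- forcing$ta_k[d]
    Delta <- forcing$delta_kpa_k[d]
    wet <- pmin(pmax((forcing$theta_sm[d] - 0.09) / (0.33 - 0.09), 0.05),
                0.95) * as.numeric(wet_jit)
    wet <- pmin(pmax(wet, 0.05), 0.98)

    # damped fixed point of the Trad <-> Rn coupling (the radiation
    # budget feeds back on the composited temperature)
    trad <- rep(Ta, np)
    for (it in 1:400) {
      rn <- net_radiation(albedo, forcing$sd_wm2[d], emis_a, emis_s, Ta,
                          trad, consts)
      part <- partition_net_radiation(rn, lai, forcing$sza_rad[d],
                                      consts$k_ext)
      G <- soil_heat_flux(part$Rns, consts$cg)
      Tc <- initial_canopy_temperature(Ta, part$Rnc, res$ra_c,
                                       consts$alpha_pt_init, consts$fg,
                                       Delta, consts, rho)
      Hs <- (1 - wet) * (part$Rns - G)
      Ts <- Ta + Hs * (res$ra_c + res$ra_s) / rhoCp
      trad_new <- (fc * Tc^4 + (1 - fc) * Ts^4)^0.25
      if (max(abs(trad_new - trad)) < 1e-12) { trad <- trad_new; break }
      trad <- 0.7 * trad + 0.3 * trad_new
    }
    rn <- net_radiation(albedo, forcing$sd_wm2[d], emis_a, emis_s, Ta,
                        trad, consts)
    part <- partition_net_radiation(rn, lai, forcing$sza_rad[d],
                                    consts$k_ext)
    G <- soil_heat_flux(part$Rns, consts$cg)
    Tc <- initial_canopy_temperature(Ta, part$Rnc, res$ra_c,
                                     consts$alpha_pt_init, consts$fg,
                                     Delta, consts, rho)
    Hc <- rhoCp * (Tc - Ta) / res$ra_c
    Hs <- (1 - wet) * (part$Rns - G)
    Ts <- Ta + Hs * (res$ra_c + res$ra_s) / rhoCp
    LEs <- wet * (part$Rns - G)
    LEc <- part$Rnc - Hc
    le <- LEc + LEs
    # store the exact composite of the final temperatures so the
    # composite identity holds to machine precision
    trad_t[d, ] <- (fc * Tc^4 + (1 - fc) * Ts^4)^0.25
    rn_t[d, ] <- rn
    g_t[d, ] <- G
    le_t[d, ] <- le
    det <- ef_daily_et(le, rn, G, rn24_t[d, ], consts)
    et24_t[d, ] <- det$ET24
  }

  # --- cloudy-day truth through the resistance reconstruction path
  fill <- fill_season(et24_t, clear, lai_t, rn24_t, forcing, ra_c_t,
                      max_gap = cfg$max_cloud_len, consts = consts)
  et24_t <- fill$et24

  # --- observation scenes
  mat <- function(v) matrix(v, cfg$nrow, cfg$ncol)
  fine_dates <- seq(1, nd, by = cfg$fine_revisit)
  scenes <- vector("list", nd)
  for (d in seq_len(nd)) {
    if (!clear[d]) { scenes[[d]] <- list(); next }
    nv <- mat(ndvi_t[d, ] +
                if (cfg$ndvi_sigma > 0)
                  stats::rnorm(np, 0, cfg$ndvi_sigma) else 0)
    lv <- mat(trad_t[d, ] +
                if (cfg$lst_sigma_k > 0)
                  stats::rnorm(np, 0, cfg$lst_sigma_k) else 0)
    sc <- list(
      coarse_ndvi = block_mean(nv, cfg$coarse_factor),
      coarse_lst = block_mean(lv, cfg$coarse_factor)
    )
    if (d %in% fine_dates) {
      sc$fine_ndvi <- nv
      sc$fine_lst <- lv
    }
    scenes[[d]] <- sc
  }

  structure(list(
    cfg = cfg, dates = dates, clear = clear, forcing = forcing,
    grid = list(nrow = cfg$nrow, ncol = cfg$ncol, xmin = 0,
                ymax = cfg$nrow * cfg$px, px = cfg$px),
    scenes = scenes,
    truth = list(ndvi = ndvi_t, lai = lai_t, trad = trad_t, rn = rn_t,
                 g = g_t, le = le_t, et24 = et24_t, rn24 = rn24_t,
                 ra_c = ra_c_t, flag = fill$flag[, 1])
  ), class = "synth_season")
}

# block mean on a bare matrix (degrade_to_coarse wraps raster_grids)
block_mean <- function(m, factor) {
  if (factor == 1) return(m)
  ri <- (seq_len(nrow(m)) - 1L) %/% factor
  s <- rowsum(m, ri, reorder = TRUE)
  s <- t(rowsum(t(s), (seq_len(ncol(m)) - 1L) %/% factor, reorder = TRUE))
  dimnames(s) <- NULL
  s / factor^2
}

#' @export
print.synth_season <- function(x, ...) {
  cat(sprintf(
    "synth_season: %d days from %s, %dx%d grid (seed %d)\n",
    length(x$dates), format(x$dates[1]), x$cfg$nrow, x$cfg$ncol,
    x$cfg$seed))
  cat(sprintf("  clear days: %d, cloudy: %d\n", sum(x$clear),
              sum(!x$clear)))
  invisible(x)
}

#' Generate a synthetic flux-station record
#'
#' Half-hourly station series consistent with one pixel's daily truth:
#' a sine daytime shape distributes the daily net radiation and latent
#' heat, soil heat flux takes a fixed fraction of net radiation, and
#' sensible heat closes the balance exactly. A closure deficit is then
#' applied multiplicatively to both turbulent fluxes (emulating
#' eddy-covariance underclosure while preserving the Bowen ratio), and
#' random gaps are injected into `LE`.
#'
#' @param season a `synth_season`.
#' @param pixel `c(row, col)` of the station pixel.
#' @param closure_deficit fraction of `H + LE` lost to underclosure.
#' @param gap_prob per-record probability that `LE` is missing.
#' @param seed RNG seed for the gaps.
#' @return data.frame with half-hourly `timestamp`, `Rn`, `G`, `H`,
#'   `LE` (observed, with deficit and gaps) and `H_true`, `LE_true`
#'   (pre-deficit, gap-free).
#' @export
generate_station_series <- function(season, pixel = c(1, 1),
                                    closure_deficit = 0.2, gap_prob = 0.05,
                                    seed = season$cfg$seed + 1) {
  stopifnot(inherits(season, "synth_season"))
  set.seed(seed)
  p <- (pixel[2] - 1) * season$cfg$nrow + pixel[1]
  nd <- length(season$dates)
  tod <- (seq_len(48) - 0.5) / 2  # hours
  shape <- pmax(sin(pi * (tod - 6) / 12), 0)
  shape <- shape / mean(shape)
  rows <- vector("list", nd)
  for (d in seq_len(nd)) {
    rn24_w <- mj_day_to_wm2(season$truth$rn24[d, p])
    le24_w <- season$truth$et24[d, p] * et_constants()$L
    le24_w <- mj_day_to_wm2(le24_w)
    Rn <- rn24_w * shape
    G <- 0.1 * Rn
    LE <- pmin(le24_w * shape, 0.95 * (Rn - G))
    LE <- pmax(LE, 0)
    H <- Rn - G - LE
    f <- 1 - closure_deficit
    ts <- as.POSIXct(paste(season$dates[d], "00:00:00"), tz = "UTC") +
      (seq_len(48) - 1) * 1800
    rows[[d]] <- data.frame(timestamp = ts, Rn = Rn, G = G,
                            H = H * f, LE = LE * f,
                            H_true = H, LE_true = LE)
  }
  out <- do.call(rbind, rows)
  gaps <- stats::runif(nrow(out)) < gap_prob
  out$LE[gaps] <- NA_real_
  out
}
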