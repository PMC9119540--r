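#' Savitzky-Golay smoothing operator as a matrix
#'
#' Dense linear operator equivalent to [sg_smooth()] on a gap-free
#' series of length `n_t`; lets a whole days-by-pixels matrix be
#' smoothed in one multiplication.
#'
#' @param n_t series length.
#' @inheritParams sg_smooth
#' @return `n_t` x `n_t` matrix `A` with `smoothed = A %*% series`.
#' @export
sg_operator <- function(n_t, window = 5, order = 2) {
  stopifnot(window %% 2 == 1, window > order, n_t >= window)
  FM <- unclass(signal::sgolay(p = order, n = window))
  k <- (window - 1) / 2
  A <- matrix(0, n_t, n_t)
  for (i in seq_len(k)) A[i, seq_len(window)] <- FM[i, ]
  mid <- FM[k + 1, ]
  for (i in (k + 1):(n_t - k)) A[i, (i - k):(i + k)] <- mid
  for (j in seq_len(k))
    A[n_t - k + j, (n_t - window + 1):n_t] <- FM[k + 1 + j, ]
  A
}

# linear gap interpolation down the rows of a days x pixels matrix
interp_gaps <- function(X) {
  idx <- seq_len(nrow(X))
  for (j in seq_len(ncol(X))) {
    ok <- is.finite(X[, j])
    if (all(ok)) next
    if (!any(ok)) stop("pixel series with no valid observation")
    X[, j] <- stats::approx(idx[ok], X[ok, j], xout = idx, rule = 2)$y
  }
  X
}

#' Pipeline parameters
#'
#' @param sg_window,sg_order Savitzky-Golay window (days, odd) and
#'   polynomial order for the NDVI time series.
#' @param max_gap maximum reconstruction distance, days; cloudy days
#'   farther than this from a clear day stay nodata.
#' @param lai_slope,lai_intercept linear LAI-NDVI calibration.
#' @param z_ref meteorological reference height, m.
#' @param fusion a [fusion_params()] object for the image-blending step.
#' @param consts physical constants from [et_constants()].
#' @return list of class `pipeline_params`.
#' @export
pipeline_params <- function(sg_window = 15, sg_order = 3, max_gap = 5,
                            lai_slope = 6, lai_intercept = -0.6,
                            z_ref = 10, fusion = fusion_params(),
                            consts = et_constants()) {
  structure(as.list(environment()), class = "pipeline_params")
}

#' Run the daily-ET pipeline over a season of scenes
#'
#' End-to-end orchestration: for every date, obtain a fine-resolution
#' NDVI and LST field (direct fine scene when available, otherwise a
#' STARFM-style blend of the nearest fine base date with the coarse
#' pair; dates with no usable LST are cloudy); smooth the NDVI series in
#' time (Savitzky-Golay) and interpolate it to daily leaf area index;
#' on clear days solve the two-source energy balance at the overpass
#' and upscale to daily ET by the evaporative fraction; on cloudy days
#' reconstruct ET through canopy-resistance scaling
#' ([fill_season()]). Deterministic given inputs.
#'
#' @param inputs season inputs: a `synth_season` or any list with
#'   `dates`, `forcing`, `grid`, `scenes` in the same layout (see
#'   [generate_season()]).
#' @param params a [pipeline_params()].
#' @return object of class `et_season`: `et24` (days x pixels, mm d-1),
#'   `flag` (days x pixels: clear / reconstructed / gap), `clear`
#'   (per-day logical), `ndvi_daily`, `lai_daily`, `rn24`, `dates`,
#'   `grid`, and a `report` with per-stage counts.
#' @export
run_pipeline <- function(inputs, params = pipeline_params()) {
  consts <- params$consts
  dates <- inputs$dates
  nd <- length(dates)
  grid <- inputs$grid
  np <- grid$nrow * grid$ncol
  forcing <- inputs$forcing
  stopifnot(nrow(forcing) == nd)
  if (is.null(forcing$rso_mj))
    forcing$rso_mj <- clearsky_radiation(
      as.integer(format(dates, "%j")),
      if (!is.null(inputs$cfg$lat_deg)) inputs$cfg$lat_deg else 36.5)

  has_fine <- vapply(inputs$scenes, function(s) !is.null(s$fine_lst),
                     logical(1))
  has_coarse <- vapply(inputs$scenes, function(s) !is.null(s$coarse_lst),
                       logical(1))

  ndvi_obs <- matrix(NA_real_, nd, np)
  lst_obs <- matrix(NA_real_, nd, np)
  n_fused <- 0L
  as_rg <- function(m, units) raster_grid(m, grid$xmin, grid$ymax,
                                          grid$px, units = units)
  as_rg_coarse <- function(m, units)
    raster_grid(m, grid$xmin, grid$ymax,
                grid$px * (grid$nrow / nrow(m)), units = units)
  base_days <- which(has_fine & has_coarse)
  for (d in seq_len(nd)) {
    sc <- inputs$scenes[[d]]
    if (has_fine[d]) {
      ndvi_obs[d, ] <- as.numeric(sc$fine_ndvi)
      lst_obs[d, ] <- as.numeric(sc$fine_lst)
    } else if (has_coarse[d] && length(base_days)) {
      b <- base_days[which.min(abs(base_days - d))]
      sb <- inputs$scenes[[b]]
      fused_n <- starfm_fuse(as_rg(sb$fine_ndvi, "ndvi"),
                             as_rg_coarse(sb$coarse_ndvi, "ndvi"),
                             as_rg_coarse(sc$coarse_ndvi, "ndvi"),
                             params$fusion)
      fused_l <- starfm_fuse(as_rg(sb$fine_lst, "K"),
                             as_rg_coarse(sb$coarse_lst, "K"),
                             as_rg_coarse(sc$coarse_lst, "K"),
                             params$fusion)
      ndvi_obs[d, ] <- as.numeric(fused_n$values)
      lst_obs[d, ] <- as.numeric(fused_l$values)
      n_fused <- n_fused + 1L
    }
  }
  clear <- rowSums(is.finite(lst_obs)) > 0

  # daily NDVI: gap-interpolate then SG-smooth the full time series;
  # short seasons shrink the window (kept odd, above the order)
  win <- min(params$sg_window, if (nd %% 2 == 1) nd else nd - 1)
  ord <- min(params$sg_order, win - 1)
  A <- sg_operator(nd, win, ord)
  ndvi_daily <- A %*% interp_gaps(ndvi_obs)
  lai_daily <- ndvi_to_lai(ndvi_daily, params$lai_slope,
                           params$lai_intercept)
  albedo_daily <- albedo_from_ndvi(ndvi_daily)

  et24 <- matrix(NA_real_, nd, np)
  rn24 <- matrix(NA_real_, nd, np)
  ra_c <- matrix(NA_real_, nd, np)
  n_fallback <- 0L
  for (d in seq_len(nd)) {
    lai <- lai_daily[d, ]
    albedo <- albedo_daily[d, ]
    h <- canopy_height_from_lai(lai)
    res <- aerodynamic_resistances(forcing$u_ms[d], params$z_ref, h, lai,
                                   consts)
    ra_c[d, ] <- res$ra_c
    rn24[d, ] <- daily_net_radiation(forcing$sd24_mj[d], albedo,
                                     forcing$ta24_k[d], forcing$ea_kpa[d],
                                     forcing$rso_mj[d])
    if (!clear[d]) next
    ok <- is.finite(lst_obs[d, ])
    fc <- fractional_cover(lai[ok])
    fx <- tseb_solve(
      Trad = lst_obs[d, ok], Ta = forcing$ta_k[d],
      Delta = forcing$delta_kpa_k[d], lai = lai[ok], fc = fc,
      fg = consts$fg, albedo = albedo[ok],
      emis_surf = surface_emissivity(fc, consts$emis_veg,
                                     consts$emis_soil),
      emis_atm = atmospheric_emissivity(forcing$ta_k[d],
                                        forcing$ea_kpa[d] * 10),
      Sd = forcing$sd_wm2[d], solar_zenith = forcing$sza_rad[d],
      ra_c = res$ra_c[ok], ra_s = res$ra_s[ok], consts = consts,
      rho = forcing$rho_kgm3[d])
    n_fallback <- n_fallback + sum(fx$fallback)
    det <- ef_daily_et(fx$LE, fx$Rn, fx$G, rn24[d, ok], consts)
    et24[d, ok] <- det$ET24
  }

  fill <- fill_season(et24, clear, lai_daily, rn24, forcing, ra_c,
                      max_gap = params$max_gap, consts = consts)

  structure(list(
    et24 = fill$et24, flag = fill$flag, rc = fill$rc,
    source_day = fill$source_day, clear = clear,
    ndvi_daily = ndvi_daily, lai_daily = lai_daily, rn24 = rn24,
    dates = dates, grid = grid,
    report = list(
      n_days = nd, n_clear = sum(clear), n_cloudy = sum(!clear),
      n_fused_scenes = n_fused, n_fallback_pixels = n_fallback,
      n_unfilled = sum(fill$flag == "gap" & !clear))
  ), class = "et_season")
}

#' @export
print.et_season <- function(x, ...) {
  r <- x$report
  cat(sprintf("et_season: %d days (%d clear, %d cloudy, %d fused scenes)\n",
              r$n_days, r$n_clear, r$n_cloudy, r$n_fused_scenes))
  cat(sprintf("  mean daily ET %.2f mm d-1; unfilled pixel-days: %d\n",
              mean(x$et24, na.rm = TRUE), r$n_unfilled))
  invisible(x)
}

#' Write / read season inputs as plain-text files
#'
#' Persists the scene stack and forcing of a season to a directory:
#' per-date ASCII grids (`fine_ndvi_YYYY-MM-DD.asc`, ...,
#' `coarse_lst_YYYY-MM-DD.asc`) plus `forcing.csv` and `config.yaml`
#' (grid geometry). `load_season_inputs()` reads the same layout back
#' into the structure [run_pipeline()] consumes.
#'
#' @param season a `synth_season` (or compatible inputs list).
#' @param dir output directory (created if missing).
#' @return `write_season_inputs` returns `dir` invisibly;
#'   `load_season_inputs` returns an inputs list.
#' @export
write_season_inputs <- function(season, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- season$grid
  utils::write.csv(season$forcing, file.path(dir, "forcing.csv"),
                   row.names = FALSE)
  yaml::write_yaml(list(grid = g, n_days = length(season$dates)),
                   file.path(dir, "config.yaml"))
  cf <- g$nrow / nrow(season$scenes[[which(
    vapply(season$scenes, function(s) !is.null(s$coarse_lst),
           logical(1)))[1]]]$coarse_lst)
  for (d in seq_along(season$dates)) {
    sc <- season$scenes[[d]]
    tag <- format(season$dates[d])
    wr <- function(m, name, px_mult) {
      if (is.null(m)) return()
      write_ascii_grid(
        raster_grid(m, g$xmin, g$ymax, g$px * px_mult),
        file.path(dir, sprintf("%s_%s.asc", name, tag)))
    }
    wr(sc$fine_ndvi, "fine_ndvi", 1)
    wr(sc$fine_lst, "fine_lst", 1)
    wr(sc$coarse_ndvi, "coarse_ndvi", cf)
    wr(sc$coarse_lst, "coarse_lst", cf)
  }
  invisible(dir)
}

#' @rdname write_season_inputs
#' @param dir directory written by [write_season_inputs()].
#' @export
load_season_inputs <- function(dir) {
  cfgf <- file.path(dir, "config.yaml")
  meta <- yaml::read_yaml(cfgf)
  forcing <- load_forcing(file.path(dir, "forcing.csv"))
  dates <- forcing$date
  scenes <- vector("list", length(dates))
  for (d in seq_along(dates)) {
    tag <- format(dates[d])
    rd <- function(name) {
      f <- file.path(dir, sprintf("%s_%s.asc", name, tag))
      if (file.exists(f)) read_ascii_grid(f)$values else NULL
    }
    sc <- list()
    for (nm in c("fine_ndvi", "fine_lst", "coarse_ndvi", "coarse_lst")) {
      v <- rd(nm)
      if (!is.null(v)) sc[[nm]] <- v
    }
    scenes[[d]] <- sc
  }
  list(dates = dates, forcing = forcing, grid = meta$grid,
       scenes = scenes)
}

#' Write the daily ET stack of a pipeline run
#'
#' One ASCII grid per day (`et24_YYYY-MM-DD.asc`) plus a per-day
#' provenance table `provenance.csv`.
#'
#' @param result an `et_season` from [run_pipeline()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_et_stack <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- result$grid
  for (d in seq_along(result$dates)) {
    m <- matrix(result$et24[d, ], g$nrow, g$ncol)
    write_ascii_grid(raster_grid(m, g$xmin, g$ymax, g$px),
                     file.path(dir, sprintf("et24_%s.asc",
                                            format(result$dates[d]))))
  }
  prov <- data.frame(
    date = result$dates,
    clear = result$clear,
    n_valid = rowSums(is.finite(result$et24)),
    n_reconstructed = rowSums(result$flag == "reconstructed"))
  utils::write.csv(prov, file.path(dir, "provenance.csv"),
                   row.names = FALSE)
  invisible(dir)
}
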