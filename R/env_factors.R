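#' Jarvis-type environmental factor parameterization
#'
#' @param sd_ref reference downward shortwave radiation at which the
#'   radiation factor saturates (same units as the `Sd` passed in).
#' @param theta_wilt,theta_crit volumetric soil moisture at wilting point
#'   and at which transpiration is unconstrained, m3 m-3
#'   (`theta_crit > theta_wilt`).
#' @param c_vpd humidity sensitivity, kPa-1.
#' @param t_opt optimal air temperature for crop growth, K (298 K).
#' @param c_ta temperature curvature, K-2.
#' @return parameter list for [jarvis_factors()].
#' @export
jarvis_params <- function(sd_ref = 25, theta_wilt = 0.09,
                          theta_crit = 0.33, c_vpd = 0.2,
                          t_opt = 298, c_ta = 0.0016) {
  if (theta_crit <= theta_wilt)
    stop("theta_crit must exceed theta_wilt")
  list(sd_ref = sd_ref, theta_wilt = theta_wilt, theta_crit = theta_crit,
       c_vpd = c_vpd, t_opt = t_opt, c_ta = c_ta)
}

#' Jarvis-type environmental factors
#'
#' Diagnostic [0, 1] stress scalars describing how solar radiation, soil
#' moisture, air humidity and air temperature constrain canopy
#' behaviour:
#' `f_sr = min(Sd / sd_ref, 1)`;
#' `f_sm = clip((theta - theta_wilt)/(theta_crit - theta_wilt), 0, 1)`;
#' `f_hu = clip(1 - c_vpd * VPD, 0, 1)`;
#' `f_ta = clip(1 - c_ta * (Ta - t_opt)^2, 0, 1)`.
#' These are a sensitivity overlay: they do not feed back into the ET
#' computation.
#'
#' @param Sd downward shortwave radiation (units of `params$sd_ref`).
#' @param theta volumetric soil moisture, m3 m-3.
#' @param VPD vapour pressure deficit, kPa.
#' @param Ta air temperature, K.
#' @param params parameter list from [jarvis_params()].
#' @return list with `f_sr`, `f_sm`, `f_hu`, `f_ta`, all in [0, 1].
#' @export
jarvis_factors <- function(Sd, theta, VPD, Ta, params = jarvis_params()) {
  clip01 <- function(x) pmin(pmax(x, 0), 1)
  list(
    f_sr = clip01(Sd / params$sd_ref),
    f_sm = clip01((theta - params$theta_wilt) /
                    (params$theta_crit - params$theta_wilt)),
    f_hu = clip01(1 - params$c_vpd * VPD),
    f_ta = clip01(1 - params$c_ta * (Ta - params$t_opt)^2)
  )
}

#' Growth-stage means of environmental factors
#'
#' Masked spatio-temporal pixel means of each factor per growth stage
#' and crop, the machinery behind stage-by-stage sensitivity tables.
#'
#' @param factors list of per-day factor fields: each element a list
#'   with `f_sr`, `f_sm`, `f_hu`, `f_ta`, each a matrix (or scalar) per
#'   day, indexed by day.
#' @param dates Date vector aligned with `factors`.
#' @param stages data.frame with columns `crop`, `stage`, `start`, `end`
#'   (Dates); stage windows must not overlap within a crop.
#' @param crop_masks named list of logical matrices (crop name ->
#'   pixel mask); scalar `TRUE` means all pixels.
#' @return data.frame with one row per crop x stage and columns
#'   `f_sm`, `f_hu`, `f_ta`, `f_sr` (pixel means; `NaN` for an empty
#'   mask/stage).
#' @export
stage_summary <- function(factors, dates, stages, crop_masks) {
  stopifnot(length(factors) == length(dates))
  rows <- lapply(seq_len(nrow(stages)), function(i) {
    crop <- stages$crop[i]
    mask <- crop_masks[[crop]]
    in_stage <- dates >= stages$start[i] & dates <= stages$end[i]
    acc <- c(f_sm = 0, f_hu = 0, f_ta = 0, f_sr = 0)
    cnt <- c(f_sm = 0, f_hu = 0, f_ta = 0, f_sr = 0)
    for (d in which(in_stage)) {
      for (f in names(acc)) {
        v <- factors[[d]][[f]]
        if (is.matrix(v) && is.matrix(mask)) v <- v[mask]
        v <- v[is.finite(v)]
        acc[f] <- acc[f] + sum(v)
        cnt[f] <- cnt[f] + length(v)
      }
    }
    m <- acc / cnt
    data.frame(crop = crop, stage = stages$stage[i],
               f_sm = m["f_sm"], f_hu = m["f_hu"],
               f_ta = m["f_ta"], f_sr = m["f_sr"],
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Default wheat/maize rotation stage calendar
#'
#' Growth-stage windows for a winter wheat (October-May) / summer maize
#' (June-September) rotation, keyed to one rotation year starting the
#' given October.
#'
#' @param start_year calendar year of the October sowing.
#' @return data.frame with columns `crop`, `stage`, `start`, `end`.
#' @export
rotation_calendar <- function(start_year) {
  y0 <- start_year; y1 <- start_year + 1
  d <- function(y, m, dd) as.Date(sprintf("%d-%02d-%02d", y, m, dd))
  data.frame(
    crop = c(rep("wheat", 5), rep("maize", 4)),
    stage = c("sowing", "wintering", "reviving", "flowering", "maturation",
              "sowing", "seeding", "flowering", "maturation"),
    start = c(d(y0, 10, 1), d(y0, 11, 1), d(y1, 2, 1), d(y1, 4, 1),
              d(y1, 5, 1), d(y1, 6, 1), d(y1, 7, 1), d(y1, 8, 1),
              d(y1, 9, 1)),
    end = c(d(y0, 10, 31), d(y1, 1, 31), d(y1, 3, 31), d(y1, 4, 30),
            d(y1, 5, 31), d(y1, 6, 30), d(y1, 7, 31), d(y1, 8, 31),
            d(y1, 9, 30))
  )
}
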