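#' Bowen-ratio energy-closure correction
#'
#' Forces half-hourly eddy-covariance turbulent fluxes to close the
#' energy balance while preserving the Bowen ratio `beta = H / LE`:
#' `LE_adj = (Rn - G) / (1 + beta)`, `H_adj = (Rn - G) * beta / (1 +
#' beta)`, so `H_adj + LE_adj = Rn - G` exactly. Records with `LE <= 0`
#' or `H + LE <= 0` (nighttime/condensation convention) are passed
#' through unadjusted and flagged.
#'
#' @param H,LE measured sensible and latent heat flux, W m-2.
#' @param Rn,G net radiation and soil heat flux, W m-2.
#' @return list with `H_adj`, `LE_adj`, `adjusted` (logical flag per
#'   record).
#' @export
bowen_ratio_closure <- function(H, LE, Rn, G) {
  ok <- is.finite(H) & is.finite(LE) & is.finite(Rn) & is.finite(G) &
    LE > 0 & (H + LE) > 0
  beta <- H / LE
  LE_adj <- ifelse(ok, (Rn - G) / (1 + beta), LE)
  H_adj <- ifelse(ok, (Rn - G) * beta / (1 + beta), H)
  list(H_adj = H_adj, LE_adj = LE_adj, adjusted = ok)
}

#' Mean-diurnal-variation gap filling
#'
#' Fills each gap in a half-hourly series with the mean of the valid
#' values at the same time of day within `window_days` days on either
#' side. Gaps whose window holds no valid value stay missing and are
#' reported via the `unfilled` attribute.
#'
#' @param series numeric vector of half-hourly values with `NA` gaps;
#'   length must be a multiple of `steps_per_day`.
#' @param window_days window half-width in days (>= 1).
#' @param steps_per_day records per day (48 for half-hourly).
#' @return filled series with attribute `unfilled` (integer indices).
#' @export
mdv_gapfill <- function(series, window_days = 7, steps_per_day = 48) {
  stopifnot(window_days >= 1, length(series) %% steps_per_day == 0)
  n_days <- length(series) / steps_per_day
  m <- matrix(series, nrow = steps_per_day)  # column = day, row = time
  out <- m
  for (j in seq_len(n_days)) {
    gaps <- which(!is.finite(m[, j]))
    if (!length(gaps)) next
    win <- max(1, j - window_days):min(n_days, j + window_days)
    for (i in gaps) {
      v <- m[i, win]
      v <- v[is.finite(v)]
      if (length(v)) out[i, j] <- mean(v)
    }
  }
  res <- as.numeric(out)
  attr(res, "unfilled") <- which(!is.finite(res))
  res
}

#' Agreement metrics between observed and simulated series
#'
#' Nash-Sutcliffe efficiency `NSE = 1 - sum((obs - sim)^2) /
#' sum((obs - mean(obs))^2)`, squared Pearson correlation `R2`,
#' `RMSE = sqrt(mean((sim - obs)^2))` and percent bias
#' `PBias = 100 * sum(obs - sim) / sum(obs)` — so model overestimation
#' yields a negative PBias. Pairs with a missing member are dropped.
#'
#' @param obs,sim numeric vectors of equal length.
#' @return list with `NSE`, `R2`, `RMSE`, `PBias`, `n`. With fewer than
#'   2 valid pairs all metrics are `NA`; with zero observed variance
#'   `NSE` and `R2` are `NA`; with constant simulation `R2` is `NA`.
#' @export
agreement_metrics <- function(obs, sim) {
  stopifnot(length(obs) == length(sim))
  ok <- is.finite(obs) & is.finite(sim)
  obs <- obs[ok]; sim <- sim[ok]
  n <- length(obs)
  if (n < 2)
    return(list(NSE = NA_real_, R2 = NA_real_, RMSE = NA_real_,
                PBias = NA_real_, n = n))
  rmse <- sqrt(mean((sim - obs)^2))
  pbias <- if (sum(obs) != 0) 100 * sum(obs - sim) / sum(obs) else NA_real_
  ss_obs <- sum((obs - mean(obs))^2)
  nse <- if (ss_obs > 0) 1 - sum((obs - sim)^2) / ss_obs else NA_real_
  r2 <- if (ss_obs > 0 && stats::sd(sim) > 0)
    stats::cor(obs, sim)^2 else NA_real_
  list(NSE = nse, R2 = r2, RMSE = rmse, PBias = pbias, n = n)
}

#' Daily ET from half-hourly latent heat
#'
#' Integrates half-hourly latent heat flux to daily ET:
#' `ET = sum(LE) * 1800 / L_J` per day with `L_J` the latent heat of
#' vaporization in J per mm of water over one square metre (2.45e6).
#'
#' @param LE half-hourly latent heat series, W m-2 (length a multiple of
#'   `steps_per_day`).
#' @param steps_per_day records per day.
#' @param L_J latent heat, J m-2 mm-1.
#' @return daily ET, mm d-1, floored at zero.
#' @export
station_daily_et <- function(LE, steps_per_day = 48, L_J = 2.45e6) {
  stopifnot(length(LE) %% steps_per_day == 0)
  m <- matrix(LE, nrow = steps_per_day)
  pmax(colSums(m) * 86400 / steps_per_day / L_J, 0)
}
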