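#' Fusion parameters
#'
#' Controls the similar-pixel search of [starfm_fuse()].
#'
#' @param window_half_size half-width of the moving search window, in fine
#'   pixels.
#' @param n_classes nominal number of land-cover classes; the similarity
#'   threshold is `spectral_tolerance * sd(fine_base) / n_classes`.
#' @param spectral_tolerance dimensionless multiplier on the class width.
#' @param max_similar_pixels cap on the number of similar pixels kept per
#'   centre (smallest combined index first); `Inf` keeps all.
#' @param eps additive regulariser (variable units) keeping the inverse
#'   spectral/temporal differences finite.
#' @return list of class `fusion_params`.
#' @export
fusion_params <- function(window_half_size = 12, n_classes = 4,
                          spectral_tolerance = 2, max_similar_pixels = Inf,
                          eps = 1e-6) {
  stopifnot(window_half_size >= 1, n_classes >= 1, spectral_tolerance > 0,
            eps > 0)
  structure(list(window_half_size = as.integer(window_half_size),
                 n_classes = as.integer(n_classes),
                 spectral_tolerance = spectral_tolerance,
                 max_similar_pixels = max_similar_pixels,
                 eps = eps),
            class = "fusion_params")
}

shift_mat <- function(M, dy, dx) {
  nr <- nrow(M); nc <- ncol(M)
  out <- matrix(NA_real_, nr, nc)
  sr <- seq_len(nr) + dy
  sc <- seq_len(nc) + dx
  ok_r <- sr >= 1 & sr <= nr
  ok_c <- sc >= 1 & sc <= nc
  out[ok_r, ok_c] <- M[sr[ok_r], sc[ok_c]]
  out
}

#' Blend a fine/coarse base pair with a coarse target image
#'
#' Predicts a fine-resolution image on a target date from one fine
#' image on a base date plus coarse images on both dates (single-pair
#' STARFM-style blending). For each fine pixel the temporal change seen by
#' the coarse sensor is averaged over spectrally similar pixels in a
#' moving window and added to the fine base value:
#' \deqn{F_t(p) = F_b(p) + \sum_c w_c [C_t(c) - C_b(c)]}
#' where candidates c are window pixels whose fine base value lies within
#' `spectral_tolerance * sd(F_b) / n_classes` of the centre value, and
#' \eqn{w_c \propto 1/[(S_c+\epsilon)(T_c+\epsilon)D_c]} combines the
#' fine/coarse spectral difference \eqn{S_c = |F_b(c) - C_b(c)|}, the
#' temporal difference \eqn{T_c = |C_t(c) - C_b(c)|} and the relative
#' distance \eqn{D_c = 1 + d_c/w}. Weights normalise to 1 per pixel, so
#' when the two coarse images agree the fine base image is returned
#' unchanged, and a uniform coarse change passes through additively.
#'
#' NDVI and LST are blended with this identical code path; only the units
#' tag and tolerance defaults differ.
#'
#' @param fine_base fine-resolution `raster_grid` on the base date.
#' @param coarse_base,coarse_target coarse `raster_grid`s sharing one
#'   grid whose pixel size is an integer multiple of the fine grid's
#'   (they are block-replicated onto the fine grid before differencing);
#'   grids already on the fine grid are accepted as-is.
#' @param params a [fusion_params()] object.
#' @return fine-resolution `raster_grid` for the target date; nodata
#'   where the centre fine pixel is nodata or no valid similar pixel
#'   exists.
#' @export
starfm_fuse <- function(fine_base, coarse_base, coarse_target,
                        params = fusion_params()) {
  stopifnot(inherits(fine_base, "raster_grid"),
            inherits(coarse_base, "raster_grid"),
            inherits(coarse_target, "raster_grid"))
  if (!same_grid(coarse_base, coarse_target))
    stop("coarse base and target images must share one grid")
  u <- c(fine_base$units, coarse_base$units, coarse_target$units)
  u <- unique(u[nzchar(u)])
  if (length(u) > 1)
    stop("unit mismatch between fusion inputs: ", paste(u, collapse = " vs "))

  ratio <- coarse_base$px / fine_base$px
  if (abs(ratio - round(ratio)) > 1e-6 || ratio < 1)
    stop("coarse pixel size must be an integer multiple of the fine size")
  ratio <- as.integer(round(ratio))
  CB <- if (ratio > 1) replicate_to_fine(coarse_base, ratio)$values
        else coarse_base$values
  CT <- if (ratio > 1) replicate_to_fine(coarse_target, ratio)$values
        else coarse_target$values
  F0 <- fine_base$values
  if (!identical(dim(CB), dim(F0)))
    stop("fine grid must nest within the coarse extent")

  w <- params$window_half_size
  th <- params$spectral_tolerance *
    stats::sd(F0[is.finite(F0)]) / params$n_classes
  if (!is.finite(th) || th <= 0) th <- params$eps
  eps <- params$eps

  if (is.finite(params$max_similar_pixels)) {
    pred <- starfm_loop(F0, CB, CT, w, th, eps, params$max_similar_pixels)
  } else {
    Wsum <- matrix(0, nrow(F0), ncol(F0))
    Wdel <- matrix(0, nrow(F0), ncol(F0))
    for (dy in -w:w) {
      for (dx in -w:w) {
        Fs <- shift_mat(F0, dy, dx)
        CBs <- shift_mat(CB, dy, dx)
        CTs <- shift_mat(CT, dy, dx)
        ok <- is.finite(Fs) & is.finite(CBs) & is.finite(CTs) &
          abs(Fs - F0) <= th
        if (!any(ok, na.rm = TRUE)) next
        S <- abs(Fs - CBs)
        Td <- abs(CTs - CBs)
        D <- 1 + sqrt(dy^2 + dx^2) / w
        wt <- 1 / ((S + eps) * (Td + eps) * D)
        wt[!ok | is.na(ok)] <- 0
        wt[is.na(wt)] <- 0
        Wsum <- Wsum + wt
        Wdel <- Wdel + wt * ifelse(is.na(CTs - CBs), 0, CTs - CBs)
      }
    }
    pred <- F0 + Wdel / Wsum
    pred[Wsum == 0] <- NA_real_
  }
  pred[!is.finite(F0)] <- NA_real_
  raster_grid(pred, xmin = fine_base$xmin, ymax = fine_base$ymax,
              px = fine_base$px, crs = fine_base$crs,
              units = fine_base$units)
}

# per-pixel search honouring the max_similar_pixels cap (small grids)
starfm_loop <- function(F0, CB, CT, w, th, eps, nmax) {
  nr <- nrow(F0); nc <- ncol(F0)
  pred <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!is.finite(F0[i, j])) next
      ii <- max(1, i - w):min(nr, i + w)
      jj <- max(1, j - w):min(nc, j + w)
      f <- F0[ii, jj]; cb <- CB[ii, jj]; ct <- CT[ii, jj]
      d <- outer(ii - i, jj - j, function(a, b) sqrt(a^2 + b^2))
      ok <- is.finite(f) & is.finite(cb) & is.finite(ct) &
        abs(f - F0[i, j]) <= th
      if (!any(ok)) next
      C <- (abs(f - cb) + eps) * (abs(ct - cb) + eps) * (1 + d / w)
      C[!ok] <- Inf
      keep <- order(C)[seq_len(min(nmax, sum(ok)))]
      wt <- 1 / C[keep]
      pred[i, j] <- F0[i, j] + sum(wt * (ct - cb)[keep]) / sum(wt)
    }
  }
  pred
}
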