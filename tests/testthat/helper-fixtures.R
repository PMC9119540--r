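# Shared fixtures: all built in code at test time.

small_season <- local({
  cache <- new.env()
  function(seed = 11, nrow = 12, ncol = 12, coarse_factor = 4,
           n_days = 60, cloud_prob = 0.15, ...) {
    key <- paste(seed, nrow, ncol, coarse_factor, n_days, cloud_prob,
                 paste(c(...), collapse = "_"), sep = "_")
    if (is.null(cache[[key]]))
      cache[[key]] <- generate_season(synth_config(
        seed = seed, nrow = nrow, ncol = ncol,
        coarse_factor = coarse_factor, n_days = n_days,
        cloud_prob = cloud_prob, ...))
    cache[[key]]
  }
})

# Exhaustive reference implementation of the fusion blend: per-pixel
# loops, no pruning, no shared code with starfm_fuse(). The prediction
# definition is fine_base(centre) + weighted mean of the coarse temporal
# difference over spectrally similar window pixels, weights
# 1 / ((S + eps) * (T + eps) * (1 + d/w)).
starfm_bruteforce <- function(F0, CB, CT, w, n_classes, tol, eps = 1e-6) {
  th <- tol * stats::sd(F0[is.finite(F0)]) / n_classes
  if (!is.finite(th) || th <= 0) th <- eps
  nr <- nrow(F0); nc <- ncol(F0)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!is.finite(F0[i, j])) next
    wsum <- 0; dsum <- 0
    for (di in -w:w) for (dj in -w:w) {
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      if (!is.finite(F0[ii, jj]) || !is.finite(CB[ii, jj]) ||
          !is.finite(CT[ii, jj])) next
      if (abs(F0[ii, jj] - F0[i, j]) > th) next
      S <- abs(F0[ii, jj] - CB[ii, jj])
      Td <- abs(CT[ii, jj] - CB[ii, jj])
      D <- 1 + sqrt(di^2 + dj^2) / w
      wt <- 1 / ((S + eps) * (Td + eps) * D)
      wsum <- wsum + wt
      dsum <- dsum + wt * (CT[ii, jj] - CB[ii, jj])
    }
    if (wsum > 0) out[i, j] <- F0[i, j] + dsum / wsum
  }
  out
}

rg <- function(m, px = 1, units = "") {
  raster_grid(as.matrix(m), xmin = 0, ymax = nrow(as.matrix(m)) * px,
              px = px, units = units)
}
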