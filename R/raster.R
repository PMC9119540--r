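#' Georeferenced raster grid
#'
#' Lightweight container for a single-band, north-up, row-major raster:
#' a numeric matrix plus an affine georeference (origin of the upper-left
#' corner and square pixel size), a free-text CRS tag and a units tag.
#' Missing data are stored as `NA`; a numeric nodata sentinel is only used
#' on disk. Row 1 is the northernmost row.
#'
#' @param values numeric matrix (rows = north to south).
#' @param xmin x coordinate of the left edge (west) of the grid.
#' @param ymax y coordinate of the top edge (north) of the grid.
#' @param px pixel size (map units per pixel), strictly positive.
#' @param crs free-text coordinate reference identifier.
#' @param units free-text unit tag for the values.
#'
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, xmin = 0, ymax = nrow(values) * px, px = 1,
                        crs = "local", units = "") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.finite(px) || px <= 0) stop("pixel size must be strictly positive")
  structure(
    list(values = values, xmin = xmin, ymax = ymax, px = px,
         crs = crs, units = units),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("raster_grid: %d x %d pixels, px = %g, origin (%g, %g)\n",
              nrow(v), ncol(v), x$px, x$xmin, x$ymax))
  cat(sprintf("  crs: %s  units: %s\n", x$crs, x$units))
  ok <- is.finite(v)
  if (any(ok)) {
    cat(sprintf("  range: [%g, %g]  valid: %d/%d\n",
                min(v[ok]), max(v[ok]), sum(ok), length(v)))
  } else {
    cat("  all nodata\n")
  }
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' Coordinates of pixel centres
#'
#' @param g a `raster_grid`.
#' @return list with numeric vectors `x` (west to east, by column) and
#'   `y` (north to south, by row).
#' @export
grid_coords <- function(g) {
  nr <- nrow(g$values); nc <- ncol(g$values)
  list(x = g$xmin + (seq_len(nc) - 0.5) * g$px,
       y = g$ymax - (seq_len(nr) - 0.5) * g$px)
}

same_grid <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymax - b$ymax) < tol &&
    abs(a$px - b$px) < tol
}

#' Read / write a raster as an ESRI ASCII grid
#'
#' Plain-text raster exchange format: a six-line header
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`)
#' followed by rows of values, north to south. `NA` cells are written as
#' the nodata sentinel. The CRS and unit tags are carried in comment-free
#' sidecar-less form only as far as the format allows, i.e. not at all;
#' callers that need them must re-attach after reading.
#'
#' @param g a `raster_grid`.
#' @param path file path (conventionally `.asc`).
#' @param nodata numeric sentinel written in place of `NA`.
#' @return `read_ascii_grid` returns a `raster_grid`;
#'   `write_ascii_grid` returns `path` invisibly.
#' @export
write_ascii_grid <- function(g, path, nodata = -9999) {
  stopifnot(inherits(g, "raster_grid"))
  v <- g$values
  nr <- nrow(v); nc <- ncol(v)
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", g$xmin),
    sprintf("yllcorner %.10g", g$ymax - nr * g$px),
    sprintf("cellsize %.10g", g$px),
    sprintf("NODATA_value %.10g", nodata)
  )
  v[!is.finite(v)] <- nodata
  body <- apply(v, 1, function(r) paste(format(r, digits = 17, trim = TRUE,
                                               scientific = FALSE),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @param crs,units tags to attach to the grid read from `path`.
#' @export
read_ascii_grid <- function(path, crs = "local", units = "") {
  lines <- readLines(path)
  if (length(lines) < 7) stop("not an ASCII grid: ", path)
  hdr <- lines[1:6]
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1))
  vals <- as.numeric(vapply(kv, `[`, "", 2))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% keys)) stop("malformed ASCII grid header in ", path)
  nc <- as.integer(vals[["ncols"]]); nr <- as.integer(vals[["nrows"]])
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"),
               what = double(), quiet = TRUE)
  if (length(body) != nr * nc) stop("ASCII grid body size mismatch in ", path)
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == vals[["nodata_value"]]] <- NA_real_
  raster_grid(m,
              xmin = vals[["xllcorner"]],
              ymax = vals[["yllcorner"]] + nr * vals[["cellsize"]],
              px = vals[["cellsize"]], crs = crs, units = units)
}

#' Bilinear resampling onto a target grid
#'
#' Resamples `src` onto the grid described by `target` (a `raster_grid`
#' whose values are ignored, or a list with `nrow`, `ncol`, `xmin`,
#' `ymax`, `px`). Each target pixel centre is interpolated from the four
#' enclosing source pixel centres; positions outside the hull of source
#' centres (but inside the source extent) are clamped to the edge row or
#' column. A target pixel becomes nodata when any contributing source
#' pixel is nodata. Bilinear interpolation reproduces affine fields
#' exactly and never extrapolates beyond the source value range.
#'
#' @param src a `raster_grid`.
#' @param target grid specification (see above).
#' @return a `raster_grid` on the target grid, carrying `src`'s tags.
#' @export
resample_bilinear <- function(src, target) {
  stopifnot(inherits(src, "raster_grid"))
  tg <- as_grid_spec(target)
  if (tg$nrow < 1 || tg$ncol < 1 || tg$px <= 0)
    stop("degenerate target grid")
  s_xmax <- src$xmin + ncol(src$values) * src$px
  s_ymin <- src$ymax - nrow(src$values) * src$px
  t_xmax <- tg$xmin + tg$ncol * tg$px
  t_ymin <- tg$ymax - tg$nrow * tg$px
  if (tg$xmin >= s_xmax || t_xmax <= src$xmin ||
      tg$ymax <= s_ymin || t_ymin >= src$ymax)
    stop("target grid does not overlap the source extent")

  tx <- tg$xmin + (seq_len(tg$ncol) - 0.5) * tg$px
  ty <- tg$ymax - (seq_len(tg$nrow) - 0.5) * tg$px
  # fractional source indices of target centres (1-based pixel centres)
  fx <- (tx - src$xmin) / src$px + 0.5
  fy <- (src$ymax - ty) / src$px + 0.5
  nrs <- nrow(src$values); ncs <- ncol(src$values)
  fx <- pmin(pmax(fx, 1), ncs)
  fy <- pmin(pmax(fy, 1), nrs)
  x0 <- pmin(floor(fx), ncs - 1L); x0[ncs == 1] <- 1
  y0 <- pmin(floor(fy), nrs - 1L); y0[nrs == 1] <- 1
  if (ncs == 1) x0 <- rep(1, length(fx))
  if (nrs == 1) y0 <- rep(1, length(fy))
  wx <- fx - x0; wy <- fy - y0
  x1 <- pmin(x0 + 1L, ncs); y1 <- pmin(y0 + 1L, nrs)

  V <- src$values
  out <- matrix(NA_real_, tg$nrow, tg$ncol)
  for (i in seq_len(tg$nrow)) {
    a <- V[cbind(y0[i], x0)] * (1 - wx) * (1 - wy[i]) +
         V[cbind(y0[i], x1)] * wx       * (1 - wy[i]) +
         V[cbind(y1[i], x0)] * (1 - wx) * wy[i] +
         V[cbind(y1[i], x1)] * wx       * wy[i]
    out[i, ] <- a
  }
  raster_grid(out, xmin = tg$xmin, ymax = tg$ymax, px = tg$px,
              crs = src$crs, units = src$units)
}

as_grid_spec <- function(target) {
  if (inherits(target, "raster_grid")) {
    list(nrow = nrow(target$values), ncol = ncol(target$values),
         xmin = target$xmin, ymax = target$ymax, px = target$px)
  } else {
    stopifnot(all(c("nrow", "ncol", "xmin", "ymax", "px") %in% names(target)))
    target
  }
}

#' Aggregate a fine raster to a coarse one by block means
#'
#' Emulates the view of a coarse-resolution sensor over a fine scene:
#' each coarse cell is the mean of a `factor` x `factor` block of fine
#' pixels. Any nodata pixel in a block makes the coarse cell nodata.
#'
#' @param fine a `raster_grid` whose dimensions are divisible by `factor`.
#' @param factor integer block edge length (>= 1).
#' @return a `raster_grid` with `factor`-times-coarser resolution.
#' @export
degrade_to_coarse <- function(fine, factor) {
  stopifnot(inherits(fine, "raster_grid"))
  factor <- as.integer(factor)
  nr <- nrow(fine$values); nc <- ncol(fine$values)
  if (factor < 1 || nr %% factor != 0 || nc %% factor != 0)
    stop("block factor must divide both raster dimensions")
  if (factor == 1) return(fine)
  v <- fine$values
  ri <- (seq_len(nr) - 1L) %/% factor
  ci <- (seq_len(nc) - 1L) %/% factor
  # group means via rowsum on both margins; NA propagates through sums
  s <- rowsum(v, ri, reorder = TRUE)
  s <- t(rowsum(t(s), ci, reorder = TRUE))
  dimnames(s) <- NULL
  raster_grid(s / factor^2, xmin = fine$xmin, ymax = fine$ymax,
              px = fine$px * factor, crs = fine$crs, units = fine$units)
}

#' Replicate coarse cells onto the nested fine grid
#'
#' Inverse plumbing of [degrade_to_coarse()]: each coarse value is
#' repeated over its `factor` x `factor` block of fine pixels (no
#' interpolation, no point-spread modelling).
#'
#' @param coarse a `raster_grid`.
#' @param factor integer block edge length.
#' @return a `raster_grid` on the fine grid.
#' @export
replicate_to_fine <- function(coarse, factor) {
  stopifnot(inherits(coarse, "raster_grid"))
  factor <- as.integer(factor)
  v <- coarse$values
  fine <- v[rep(seq_len(nrow(v)), each = factor),
            rep(seq_len(ncol(v)), each = factor), drop = FALSE]
  raster_grid(fine, xmin = coarse$xmin, ymax = coarse$ymax,
              px = coarse$px / factor, crs = coarse$crs, units = coarse$units)
}
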