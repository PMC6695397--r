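#' Normalised difference vegetation index
#'
#' `NDVI = (B8 - B4) / (B8 + B4)`, computed from the near-infrared (B8)
#' and red (B4) bands of a composite; where `B8 + B4 = 0` the index is
#' undefined and set missing.
#'
#' @param composite A `pc_raster` containing bands `B8` and `B4`.
#' @return A single-band `pc_raster` in `[-1, 1]` where defined.
#' @export
ndvi <- function(composite) {
  nir <- band(composite, "B8"); red <- band(composite, "B4")
  den <- nir + red
  out <- (nir - red) / den
  out[!is.na(den) & den == 0] <- NA_real_
  pc_raster(out, res = composite$res, xmin = composite$xmin,
            ymax = composite$ymax, crs = composite$crs)
}

#' Moving-window standard deviation (texture)
#'
#' Per-pixel population standard deviation over an odd square window.
#' At image edges the window shrinks to the in-bounds pixels (no values
#' are invented outside the image); missing cells are excluded from the
#' window statistics, and a pixel whose window holds no valid cell is
#' missing.
#'
#' @param x A single-band `pc_raster` or a matrix.
#' @param window Odd window side >= 3 (default 5, i.e. 5 x 5).
#' @return Same type as `x`, holding the windowed standard deviation.
#' @export
moving_sd <- function(x, window = 5) {
  window <- as.integer(window)
  if (window < 1 || window %% 2L == 0L)
    stopf("`window` must be an odd positive integer (got %d)", window)
  m <- if (inherits(x, "pc_raster")) x$values else x
  if (!is.matrix(m)) stopf("`x` must be a matrix or single-band pc_raster")
  if (window == 1L) {
    out <- matrix(0, nrow(m), ncol(m)); out[is.na(m)] <- NA_real_
  } else {
    # centre the data first so constants give an exact zero
    ws <- window_sums(m - mean(m, na.rm = TRUE), window)
    mu <- ws$sum / ws$n
    va <- pmax(ws$sumsq / ws$n - mu * mu, 0)
    out <- sqrt(va)
    out[ws$n == 0] <- NA_real_
  }
  if (inherits(x, "pc_raster"))
    pc_raster(out, res = x$res, xmin = x$xmin, ymax = x$ymax, crs = x$crs)
  else out
}

#' Terrain slope in degrees
#'
#' Slope from a projected-DEM 3 x 3 finite-difference gradient (Horn's
#' weighting); border cells reuse the nearest in-bounds row/column
#' (edge replication), so a flat DEM is 0 everywhere and an inclined
#' plane recovers its analytic slope on interior pixels.
#'
#' @param dem A single-band `pc_raster` of elevations (metres) on a
#'   metric (projected) grid.
#' @param cellsize Cell size in metres; defaults to the raster's.
#' @return A `pc_raster` of slope in degrees, `[0, 90)`.
#' @export
slope <- function(dem, cellsize = NULL) {
  if (!inherits(dem, "pc_raster")) stopf("`dem` must be a pc_raster")
  if (identical(dem$crs, "geographic"))
    stopf("slope requires a projected (metre-unit) DEM, not geographic degrees")
  cs <- cellsize %||% dem$res
  z <- dem$values
  zs <- function(dr, dc) shift_clamp(z, dr, dc)
  # matrix rows run north -> south: row + 1 is one cell south
  gx <- ((zs(-1, 1) + 2 * zs(0, 1) + zs(1, 1)) -
           (zs(-1, -1) + 2 * zs(0, -1) + zs(1, -1))) / (8 * cs)
  gy <- ((zs(-1, -1) + 2 * zs(-1, 0) + zs(-1, 1)) -
           (zs(1, -1) + 2 * zs(1, 0) + zs(1, 1))) / (8 * cs)
  deg <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  pc_raster(deg, res = dem$res, xmin = dem$xmin, ymax = dem$ymax,
            crs = dem$crs)
}

resample_to_grid <- function(m, in_res, out_res, out_dim, grid_meta) {
  if (in_res == out_res) return(m)
  fact <- out_res / in_res
  if (abs(fact - round(fact)) < 1e-9) return(block_aggregate(m, round(fact)))
  r <- pc_raster(m, res = in_res, xmin = grid_meta$xmin, ymax = grid_meta$ymax,
                 crs = grid_meta$crs)
  resample_bilinear(r, out_res, out_dim)$values
}

#' Assemble the 17-band feature stack on the analysis grid
#'
#' Resamples every predictor to the common analysis grid and stacks them
#' in the fixed order `B2..B12, NDVI, NDVI_SD5, VV_mean, VV_sd, VH_mean,
#' VH_sd, SLOPE`. Integer-ratio downsampling (e.g. 10 m to 20 m) uses
#' the block mean; non-nested grids (the 30 m slope) are interpolated
#' bilinearly. Any pixel missing in any optical composite band is
#' missing in every layer of the output.
#'
#' @param composite 10-band optical composite (`pc_raster`, native grid).
#' @param ndvi_r Single-band NDVI `pc_raster` (native grid).
#' @param texture_r Single-band NDVI-texture `pc_raster` (native grid).
#' @param sar_stats 4-band radar statistics `pc_raster` (native grid).
#' @param slope_r Single-band slope `pc_raster` (its own grid).
#' @param out_res Analysis cell size in metres (default 20).
#' @return A 17-band `pc_raster` on the analysis grid.
#' @export
build_feature_stack <- function(composite, ndvi_r, texture_r, sar_stats,
                                slope_r, out_res = 20) {
  for (r in list(composite, ndvi_r, texture_r, sar_stats, slope_r)) {
    if (!inherits(r, "pc_raster")) stopf("all inputs must be pc_raster objects")
    if (!identical(r$crs, composite$crs))
      stopf("CRS mismatch among inputs; reproject before stacking")
  }
  fact <- out_res / composite$res
  if (abs(fact - round(fact)) > 1e-9)
    stopf("analysis resolution must be an integer multiple of the composite's")
  d_in <- dim(composite$values)
  out_dim <- c(d_in[1] %/% round(fact), d_in[2] %/% round(fact))
  meta <- list(xmin = composite$xmin, ymax = composite$ymax, crs = composite$crs)
  nms <- feature_names()
  arr <- array(NA_real_, dim = c(out_dim, length(nms)),
               dimnames = list(NULL, NULL, nms))
  for (b in optical_bands())
    arr[, , b] <- resample_to_grid(band(composite, b), composite$res, out_res,
                                   out_dim, meta)
  arr[, , "NDVI"] <- resample_to_grid(ndvi_r$values, ndvi_r$res, out_res,
                                      out_dim, meta)
  arr[, , "NDVI_SD5"] <- resample_to_grid(texture_r$values, texture_r$res,
                                          out_res, out_dim, meta)
  for (b in c("VV_mean", "VV_sd", "VH_mean", "VH_sd"))
    arr[, , b] <- resample_to_grid(band(sar_stats, b), sar_stats$res, out_res,
                                   out_dim, meta)
  sl <- resample_to_grid(slope_r$values, slope_r$res, out_res, out_dim,
                         list(xmin = slope_r$xmin, ymax = slope_r$ymax,
                              crs = slope_r$crs))
  arr[, , "SLOPE"] <- sl[seq_len(out_dim[1]), seq_len(out_dim[2])]
  # nodata in any optical layer voids the pixel throughout
  bad <- matrix(FALSE, out_dim[1], out_dim[2])
  for (b in optical_bands()) bad <- bad | is.na(arr[, , b])
  if (any(bad)) for (b in nms) { pl <- arr[, , b]; pl[bad] <- NA_real_; arr[, , b] <- pl }
  pc_raster(arr, res = out_res, xmin = composite$xmin, ymax = composite$ymax,
            crs = composite$crs)
}
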