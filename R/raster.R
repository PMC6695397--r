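#' Lightweight in-memory raster
#'
#' `palmcover` represents rasters as plain matrices (single band) or
#' row x col x band arrays (multi-band) wrapped with the minimal grid
#' metadata the pipeline needs: a square cell size in metres, the
#' coordinate of the upper-left corner, and a CRS tag. Row 1 is the
#' northernmost row; the centre of pixel (r, c) is at
#' `x = xmin + (c - 0.5) * res`, `y = ymax - (r - 0.5) * res`.
#'
#' @param values A numeric matrix, or a 3-D array with bands along the
#'   third dimension (named via `dimnames`).
#' @param res Cell size in metres (> 0).
#' @param xmin,ymax Coordinates of the upper-left corner. `ymax` defaults
#'   to `nrow * res` so the extent starts at the origin.
#' @param crs Either `"metric"` (projected, metre units) or
#'   `"geographic"`. Terrain functions require a metric grid.
#' @return An object of class `pc_raster`.
#' @export
pc_raster <- function(values, res, xmin = 0, ymax = NULL, crs = "metric") {
  if (!(is.matrix(values) || (is.array(values) && length(dim(values)) == 3)))
    stopf("`values` must be a matrix or a 3-D array")
  if (!is.numeric(res) || length(res) != 1 || res <= 0)
    stopf("`res` must be a single positive cell size in metres")
  if (is.null(ymax)) ymax <- nrow(values) * res
  structure(
    list(values = values, res = res, xmin = xmin, ymax = ymax, crs = crs),
    class = "pc_raster"
  )
}

#' @export
dim.pc_raster <- function(x) dim(x$values)

#' @export
print.pc_raster <- function(x, ...) {
  d <- dim(x$values)
  nb <- if (length(d) == 3) d[3] else 1L
  cat(sprintf("<pc_raster> %d x %d pixels, %d band(s), %g m cells\n",
              d[1], d[2], nb, x$res))
  if (!is.null(band_names(x))) cat("bands:", paste(band_names(x), collapse = ", "), "\n")
  rng <- suppressWarnings(range(x$values, na.rm = TRUE))
  cat(sprintf("extent: x [%g, %g], y [%g, %g]; values [%g, %g]\n",
              x$xmin, x$xmin + d[2] * x$res, x$ymax - d[1] * x$res, x$ymax,
              rng[1], rng[2]))
  invisible(x)
}

#' Band names of a multi-band raster
#' @param x A `pc_raster`.
#' @return Character vector of band names, or `NULL` for unnamed bands.
#' @export
band_names <- function(x) {
  if (length(dim(x$values)) == 3) dimnames(x$values)[[3]] else NULL
}

#' Extract one band as a matrix
#' @param x A `pc_raster`.
#' @param name Band name (3-D rasters) or ignored for single-band rasters.
#' @export
band <- function(x, name) {
  if (length(dim(x$values)) == 2) return(x$values)
  nms <- band_names(x)
  if (is.null(nms) || !name %in% nms)
    stopf("band '%s' not present (have: %s)", name,
          paste(nms %||% "<unnamed>", collapse = ", "))
  v <- x$values[, , name, drop = FALSE]
  dim(v) <- dim(v)[1:2]
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pixel-centre coordinates
#'
#' @param x A `pc_raster`.
#' @return A two-column matrix (x, y) in row-major pixel order, i.e.
#'   `cbind(as.vector(col-x), as.vector(row-y))` matching `as.vector()`
#'   of a band matrix (column-major).
#' @export
pixel_centers <- function(x) {
  d <- dim(x$values)
  xs <- x$xmin + (seq_len(d[2]) - 0.5) * x$res
  ys <- x$ymax - (seq_len(d[1]) - 0.5) * x$res
  cbind(x = rep(xs, each = d[1]), y = rep(ys, times = d[2]))
}

# result[r, c] = m[r + dr, c + dc]; out-of-bounds -> fill
shift_mat <- function(m, dr, dc, fill = NA_real_) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  r0 <- max(1, 1 - dr); r1 <- min(nr, nr - dr)
  c0 <- max(1, 1 - dc); c1 <- min(nc, nc - dc)
  if (r0 <= r1 && c0 <= c1)
    out[r0:r1, c0:c1] <- m[(r0 + dr):(r1 + dr), (c0 + dc):(c1 + dc),
                           drop = FALSE]
  out
}

# as shift_mat but indices clamped to the border (edge replication)
shift_clamp <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  m[pmin(pmax(seq_len(nr) + dr, 1), nr), pmin(pmax(seq_len(nc) + dc, 1), nc)]
}

# moving-window sums of values, squares and valid counts (window shrinks at
# edges; NA cells contribute nothing)
window_sums <- function(m, window) {
  h <- (window - 1L) / 2L
  v <- m; v[is.na(v)] <- 0
  ok <- !is.na(m)
  s1 <- s2 <- matrix(0, nrow(m), ncol(m))
  nn <- matrix(0L, nrow(m), ncol(m))
  okn <- ok * 1
  v2 <- v * v
  for (dr in -h:h) for (dc in -h:h) {
    s1 <- s1 + shift_mat(v, dr, dc, fill = 0)
    s2 <- s2 + shift_mat(v2, dr, dc, fill = 0)
    nn <- nn + shift_mat(okn, dr, dc, fill = 0)
  }
  list(sum = s1, sumsq = s2, n = nn)
}

#' Block-mean aggregation
#'
#' Aggregates a matrix by an integer factor, each output cell the mean of
#' the valid (non-missing) input cells in its `fact` x `fact` block; a
#' block with no valid cell is missing. Conserves the spatial mean on
#' fully valid, exactly nested grids.
#'
#' @param m Numeric matrix whose dimensions are multiples of `fact`.
#' @param fact Positive integer aggregation factor.
#' @return A `nrow(m)/fact` x `ncol(m)/fact` matrix.
#' @export
block_aggregate <- function(m, fact) {
  fact <- as.integer(fact)
  if (fact < 1) stopf("`fact` must be a positive integer")
  if (fact == 1L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  if (nr %% fact != 0 || nc %% fact != 0)
    stopf("raster dimensions (%d x %d) are not a multiple of fact = %d", nr, nc, fact)
  v <- m; v[is.na(v)] <- 0
  ok <- (!is.na(m)) * 1
  collapse_rows <- function(x) {
    a <- array(x, dim = c(fact, nr %/% fact, nc))
    colSums(a)
  }
  s <- collapse_rows(v); k <- collapse_rows(ok)
  collapse_cols <- function(x) {
    a <- array(t(x), dim = c(fact, nc %/% fact, nr %/% fact))
    t(colSums(a))
  }
  s <- collapse_cols(s); k <- collapse_cols(k)
  out <- s / k
  out[k == 0] <- NA_real_
  out
}

#' Bilinear resampling between aligned grids
#'
#' Resamples a single-band raster to a target resolution over the same
#' extent origin, interpolating linearly between source cell centres and
#' clamping target points outside the source centre lattice to the edge.
#'
#' @param r A single-band `pc_raster`.
#' @param out_res Target cell size (metres).
#' @param out_dim Optional target `c(nrow, ncol)`; defaults to the number
#'   of whole target cells covering the source extent.
#' @return A `pc_raster` at the target resolution.
#' @export
resample_bilinear <- function(r, out_res, out_dim = NULL) {
  m <- r$values
  if (length(dim(m)) != 2) stopf("`resample_bilinear()` expects a single band")
  d <- dim(m)
  if (is.null(out_dim))
    out_dim <- c(floor(d[1] * r$res / out_res), floor(d[2] * r$res / out_res))
  # source centre coordinates, ascending
  xs <- r$xmin + (seq_len(d[2]) - 0.5) * r$res
  ys_desc <- r$ymax - (seq_len(d[1]) - 0.5) * r$res
  ys <- rev(ys_desc)
  m_flip <- m[rev(seq_len(d[1])), , drop = FALSE]
  xt <- r$xmin + (seq_len(out_dim[2]) - 0.5) * out_res
  yt <- r$ymax - (seq_len(out_dim[1]) - 0.5) * out_res
  xp <- rep(pmin(pmax(xt, min(xs)), max(xs)), each = out_dim[1])
  yp <- rep(pmin(pmax(yt, min(ys)), max(ys)), times = out_dim[2])
  vals <- pracma::interp2(xs, ys, m_flip, xp, yp, method = "linear")
  pc_raster(matrix(vals, out_dim[1], out_dim[2]), res = out_res,
            xmin = r$xmin, ymax = r$ymax, crs = r$crs)
}

#' Write / read a raster as TIFF with a JSON georeferencing sidecar
#'
#' Values are min-max scaled into `[0, 1]` for the TIFF container; the
#' sidecar (`<path>.json`) records the affine grid, band names, the scale
#' and any missing-cell indices so `read_raster_tiff()` round-trips the
#' raster exactly to float-32 precision.
#'
#' @param x A `pc_raster`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_raster_tiff <- function(x, path) {
  v <- x$values
  if (length(dim(v)) == 2) v <- array(v, dim = c(dim(v), 1))
  na_idx <- which(is.na(v))
  rng <- range(v, na.rm = TRUE)
  if (!all(is.finite(rng))) rng <- c(0, 1)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  vs <- (v - rng[1]) / scale
  vs[na_idx] <- 0
  planes <- lapply(seq_len(dim(vs)[3]), function(b) vs[, , b])
  tiff::writeTIFF(planes, path, bits.per.sample = 32L)
  meta <- list(res = x$res, xmin = x$xmin, ymax = x$ymax, crs = x$crs,
               bands = dimnames(x$values)[[3]] %||% band_names(x),
               vmin = rng[1], vscale = scale, na_idx = na_idx,
               dim = dim(x$values))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_raster_tiff
#' @export
read_raster_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  planes <- tiff::readTIFF(path, all = TRUE)
  v <- array(unlist(planes), dim = c(dim(planes[[1]]), length(planes)))
  v <- v * meta$vscale + meta$vmin
  if (length(meta$na_idx)) v[meta$na_idx] <- NA_real_
  dim(v) <- meta$dim
  if (!is.null(meta$bands) && length(dim(v)) == 3)
    dimnames(v) <- list(NULL, NULL, meta$bands)
  pc_raster(v, res = meta$res, xmin = meta$xmin, ymax = meta$ymax, crs = meta$crs)
}
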