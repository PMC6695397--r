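#' Polygon tables
#'
#' Vector layers are tibbles with a `geometry` list-column of two-column
#' (x, y) coordinate matrices — one simple ring per row, in the same
#' projected metric coordinates as the rasters. Reference polygons carry
#' `polygon_id` and `class_id`; zones carry `zone_id` and `kind`
#' (`"concession"`, `"district"` or `"park"`).
#'
#' @param xmin,ymin,xmax,ymax Rectangle bounds.
#' @return A closed 5 x 2 coordinate matrix (counter-clockwise).
#' @export
rect_ring <- function(xmin, ymin, xmax, ymax) {
  cbind(x = c(xmin, xmax, xmax, xmin, xmin),
        y = c(ymin, ymin, ymax, ymax, ymin))
}

close_ring <- function(ring) {
  if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  ring
}

#' Point-in-polygon test
#'
#' Tests which points fall inside a polygon ring (even-odd rule, via
#' [mgcv::in.out()]).
#'
#' @param pts Two-column matrix of point coordinates.
#' @param ring Two-column coordinate matrix of the polygon boundary.
#' @return Logical vector, one element per point.
#' @export
points_in_polygon <- function(pts, ring) {
  ring <- close_ring(as.matrix(ring))
  if (nrow(pts) == 0) return(logical(0))
  mgcv::in.out(ring, as.matrix(pts))
}

# logical matrix (raster shape): TRUE where the pixel centre is inside
polygon_pixel_mask <- function(r, ring) {
  d <- dim(r$values)[1:2]
  ring <- as.matrix(ring)
  # restrict the test to the ring's bounding box for speed
  xs <- r$xmin + (seq_len(d[2]) - 0.5) * r$res
  ys <- r$ymax - (seq_len(d[1]) - 0.5) * r$res
  cok <- which(xs >= min(ring[, 1]) & xs <= max(ring[, 1]))
  rok <- which(ys >= min(ring[, 2]) & ys <= max(ring[, 2]))
  mask <- matrix(FALSE, d[1], d[2])
  if (!length(cok) || !length(rok)) return(mask)
  pts <- cbind(rep(xs[cok], each = length(rok)), rep(ys[rok], times = length(cok)))
  mask[rok, cok] <- points_in_polygon(pts, ring)
  mask
}

#' Write / read polygon tables as GeoJSON
#'
#' Serialises a polygon tibble to a GeoJSON `FeatureCollection` (one
#' `Polygon` feature per row; all non-geometry columns become feature
#' properties) and reads it back.
#'
#' @param tbl Polygon tibble with a `geometry` list-column.
#' @param path Output path.
#' @return `path` invisibly; `read_polygons_geojson()` returns the tibble.
#' @export
write_polygons_geojson <- function(tbl, path) {
  props <- tbl[setdiff(names(tbl), "geometry")]
  feats <- lapply(seq_len(nrow(tbl)), function(i) {
    ring <- close_ring(as.matrix(tbl$geometry[[i]]))
    list(
      type = "Feature",
      properties = as.list(props[i, , drop = FALSE]),
      geometry = list(type = "Polygon",
                      coordinates = list(lapply(seq_len(nrow(ring)),
                                                function(j) unname(ring[j, ]))))
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_polygons_geojson
#' @export
read_polygons_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  rows <- lapply(gj$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) as.numeric(unlist(p))))
    colnames(ring) <- c("x", "y")
    c(f$properties, list(geometry = list(ring)))
  })
  out <- bind_rows(lapply(rows, function(r) {
    tb <- as_tibble(r[setdiff(names(r), "geometry")])
    tb$geometry <- r$geometry
    tb
  }))
  out
}
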