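class_palette <- function() {
  c(oil_palm = "#b07c2a", rubber = "#7a4fa3", other_trees = "#1a6b2a",
    shrub = "#a8c44f", bare = "#d9c3a3", water = "#2f6db3")
}

raster_df <- function(r, value_name = "value") {
  d <- dim(r$values)[1:2]
  xy <- pixel_centers(r)
  out <- tibble(x = xy[, 1], y = xy[, 2],
                value = as.vector(if (length(dim(r$values)) == 3)
                  r$values[, , 1] else r$values))
  names(out)[3] <- value_name
  out
}

#' Plot a class map
#'
#' @param map A `pc_raster` integer class map.
#' @return A ggplot object.
#' @export
plot_class_map <- function(map) {
  df <- raster_df(map, "class_id")
  cn <- lc_classes()
  df$class_name <- factor(cn$class_name[df$class_id], levels = cn$class_name)
  ggplot(df[!is.na(df$class_id), ], aes(.data$x, .data$y, fill = .data$class_name)) +
    geom_raster() +
    scale_fill_manual(values = class_palette(), name = "class") +
    coord_equal() +
    labs(x = "easting (m)", y = "northing (m)") +
    theme_minimal()
}

#' @export
autoplot.pc_raster <- function(object, ...) {
  v <- if (length(dim(object$values)) == 3) object$values[, , 1] else object$values
  if (is.integer(v) && all(v[!is.na(v)] %in% 1:6)) return(plot_class_map(object))
  df <- raster_df(object)
  ggplot(df, aes(.data$x, .data$y, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c() +
    coord_equal() +
    labs(x = "easting (m)", y = "northing (m)") +
    theme_minimal()
}

#' @export
autoplot.pc_area_estimate <- function(object, truth = NULL, ...) {
  df <- as_tibble(object)
  df$class_name <- factor(df$class_name, levels = df$class_name)
  p <- ggplot(df, aes(.data$class_name, .data$area_ha)) +
    geom_col(aes(fill = .data$class_name), show.legend = FALSE) +
    geom_errorbar(aes(ymin = .data$ci_lo_ha, ymax = .data$ci_hi_ha),
                  width = 0.25) +
    scale_fill_manual(values = class_palette()) +
    labs(x = NULL, y = "error-adjusted area (ha, 95% CI)") +
    theme_minimal()
  if (!is.null(truth))
    p <- p + geom_point(data = truth,
                        aes(.data$class_name, .data$true_area_ha),
                        shape = 4, size = 3)
  p
}

#' @export
autoplot.pc_error_matrix <- function(object, ...) {
  df <- as_tibble(as.data.frame(object$counts, responseName = "n"))
  names(df)[1:2] <- c("map", "reference")
  ggplot(df, aes(.data$reference, .data$map, fill = .data$n)) +
    geom_tile() +
    scale_fill_viridis_c(name = "count") +
    labs(x = "reference class", y = "mapped class") +
    theme_minimal()
}
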