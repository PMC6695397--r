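#' Per-zone class areas and shares
#'
#' Overlays a class map with zone polygons. A pixel belongs to a zone
#' iff its centre lies inside the zone geometry; counts times the pixel
#' area give hectares, and shares are of the zone's mapped (non-missing)
#' area. Zones of different kinds may overlap — a pixel is counted in
#' each kind it falls in — while same-kind accounting should go through
#' [kind_class_areas()], which unions the kind's zones first so no pixel
#' is double-counted within a kind.
#'
#' @param map A `pc_raster` class map.
#' @param zones Zone tibble (`zone_id`, `kind`, `geometry`).
#' @param pixel_area Pixel area in hectares.
#' @return A `ZonalSummary` tibble: one row per (zone, class) with
#'   `zone_id`, `kind`, `class_id`, `class_name`, `pixel_count`,
#'   `area_ha`, `share`.
#' @export
zonal_class_areas <- function(map, zones, pixel_area) {
  cn <- lc_classes()
  out <- vector("list", nrow(zones))
  for (i in seq_len(nrow(zones))) {
    mask <- polygon_pixel_mask(map, zones$geometry[[i]])
    vals <- map$values[mask]
    vals <- vals[!is.na(vals)]
    if (!length(vals))
      warn(sprintf("zone %s covers no mapped pixel centre", zones$zone_id[i]))
    cnt <- tabulate(vals, nbins = nrow(cn))
    out[[i]] <- tibble(zone_id = zones$zone_id[i], kind = zones$kind[i],
                       class_id = cn$class_id, class_name = cn$class_name,
                       pixel_count = cnt,
                       area_ha = cnt * pixel_area,
                       share = if (sum(cnt) > 0) cnt / sum(cnt) else rep(0, nrow(cn)))
  }
  bind_rows(out)
}

#' Class areas within the union of one zone kind
#'
#' Counts each pixel once if it falls inside any zone of the requested
#' kind (overlapping same-kind zones are effectively unioned).
#'
#' @inheritParams zonal_class_areas
#' @param kind `"concession"`, `"district"` or `"park"`.
#' @return A tibble: `class_id`, `class_name`, `pixel_count`, `area_ha`,
#'   `share`.
#' @export
kind_class_areas <- function(map, zones, pixel_area, kind = "concession") {
  sel <- zones[zones$kind == kind, ]
  if (!nrow(sel)) stopf("no zones of kind '%s'", kind)
  member <- matrix(FALSE, nrow(map$values), ncol(map$values))
  for (i in seq_len(nrow(sel)))
    member <- member | polygon_pixel_mask(map, sel$geometry[[i]])
  vals <- map$values[member]
  vals <- vals[!is.na(vals)]
  cn <- lc_classes()
  cnt <- tabulate(vals, nbins = nrow(cn))
  tibble(class_id = cn$class_id, class_name = cn$class_name,
         pixel_count = cnt, area_ha = cnt * pixel_area,
         share = if (sum(cnt) > 0) cnt / sum(cnt) else rep(0, nrow(cn)))
}

#' Class shares of the concession area
#'
#' Percentage of the total concession area (the six-class sum) occupied
#' by each class. Accepts either a zonal/kind summary restricted to
#' concessions or any tibble of per-class areas.
#'
#' @param x A tibble with `class_name` (or `class_id`) and `area_ha`;
#'   if a `kind` column is present only `kind == "concession"` rows are
#'   used, and multiple zones are summed per class.
#' @param digits Rounding for the reported percentage (default 0 =
#'   nearest percent, the convention of the published tables).
#' @return A tibble: `class_name`, `area_ha`, `share`, `share_pct`
#'   (rounded).
#' @export
concession_shares <- function(x, digits = 0) {
  if ("kind" %in% names(x)) x <- x[x$kind == "concession", ]
  if (!nrow(x)) stopf("no concession rows in `x`")
  key <- if ("class_name" %in% names(x)) "class_name" else "class_id"
  agg <- x |>
    group_by(across(dplyr::all_of(key))) |>
    summarise(area_ha = sum(.data$area_ha), .groups = "drop")
  den <- sum(agg$area_ha)
  if (den <= 0) stopf("total concession area is zero")
  agg$share <- agg$area_ha / den
  agg$share_pct <- round(100 * agg$share, digits)
  agg
}

#' Inside/outside-concession split of class areas
#'
#' @param total Tibble of region-wide per-class areas (`class_name`,
#'   `area_ha`).
#' @param concession Tibble of within-concession per-class areas (same
#'   columns).
#' @return A tibble: `class_name`, `total_ha`, `inside_ha`, `outside_ha`
#'   (`total - inside`), `inside_pct`.
#' @export
inside_outside_split <- function(total, concession) {
  j <- left_join(
    tibble(class_name = total$class_name, total_ha = total$area_ha),
    tibble(class_name = concession$class_name, inside_ha = concession$area_ha),
    by = "class_name"
  )
  j$inside_ha[is.na(j$inside_ha)] <- 0
  bad <- j$inside_ha > j$total_ha
  if (any(bad))
    stopf("inconsistent areas: inside > total for class '%s'",
          paste(j$class_name[bad], collapse = "', '"))
  j$outside_ha <- j$total_ha - j$inside_ha
  j$inside_pct <- ifelse(j$total_ha > 0, 100 * j$inside_ha / j$total_ha, NA_real_)
  j
}

#' Carbon-emission risk of clearing an area
#'
#' Converts a vegetated area and its aboveground carbon density into the
#' CO2-equivalent mass that clearing would release:
#' `co2e_tg = area_ha * carbon_density * conversion / 1e6`, with the
#' molar-mass ratio CO2/C = 44/12 as the default conversion factor.
#'
#' @param area_ha Area in hectares (>= 0).
#' @param carbon_density Aboveground carbon stock, Mg C per hectare.
#' @param conversion Mass ratio CO2 per C (default exactly 44/12).
#' @return A tibble: inputs plus `co2e_mg` (Mg CO2e) and `co2e_tg`
#'   (Tg CO2e).
#' @export
emissions <- function(area_ha, carbon_density, conversion = 44 / 12) {
  if (any(area_ha < 0) || any(carbon_density < 0) || any(conversion < 0))
    stopf("emissions inputs must be non-negative")
  co2e_mg <- area_ha * carbon_density * conversion
  tibble(area_ha = area_ha, carbon_density_mgc_ha = carbon_density,
         conversion_factor = conversion,
         co2e_mg = co2e_mg, co2e_tg = co2e_mg / 1e6)
}

#' Acres to hectares
#'
#' @param acres Area in international acres (>= 0).
#' @param digits Optional rounding (`0` = nearest hectare); `NULL` leaves
#'   the value unrounded.
#' @return Hectares.
#' @export
acres_to_hectares <- function(acres, digits = NULL) {
  if (any(acres < 0)) stopf("`acres` must be >= 0")
  ha <- acres * 0.40468564224
  if (!is.null(digits)) ha <- round(ha, digits)
  ha
}

#' Published six-class area estimates for the mapped region
#'
#' The bias-corrected area estimates (hectares) published for the
#' southern-Myanmar plantation region the pipeline's accounting stage is
#' designed around: region-wide totals and the within-concession portion
#' for each of the six classes. These printed values feed the worked
#' share/ratio/emissions examples without requiring any imagery.
#'
#' @return A tibble: `class_name`, `total_ha`, `concession_ha`.
#' @export
published_area_estimates <- function() {
  path <- system.file("extdata", "regional_area_estimates.csv",
                      package = "palmcover", mustWork = TRUE)
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
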