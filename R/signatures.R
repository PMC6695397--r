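#' The six mapped land-cover classes
#'
#' Integer codes and names for the classes the pipeline maps: oil palm,
#' rubber, other trees (forests, tree plantations and tree-crops other
#' than the two target crops), shrub (grassland, open canopy, young and
#' low vegetation), bare land and water.
#'
#' @return A tibble with `class_id` (1..6) and `class_name`.
#' @export
lc_classes <- function() {
  tibble(class_id = 1:6,
         class_name = c("oil_palm", "rubber", "other_trees",
                        "shrub", "bare", "water"))
}

#' Optical band names of the feature stack
#' @return Character vector of the ten optical band names (blue through
#'   short-wave infrared, including the four red-edge bands).
#' @export
optical_bands <- function() {
  c("B2", "B3", "B4", "B5", "B6", "B7", "B8", "B8A", "B11", "B12")
}

#' Full 17-layer feature order
#' @return Character vector naming the 17 predictors in stack order.
#' @export
feature_names <- function() {
  c(optical_bands(), "NDVI", "NDVI_SD5", "VV_mean", "VV_sd",
    "VH_mean", "VH_sd", "SLOPE")
}

#' Default spectral and radar class signatures
#'
#' Per-class band means and noise standard deviations used by the
#' synthetic-scene generator: top-of-atmosphere-style reflectance
#' (dimensionless, 0-1) for the ten optical bands and backscatter (dB)
#' for the two radar polarisations. The defaults make oil palm and
#' rubber deliberately close in the visible bands and separable mainly
#' through the red-edge region and radar backscatter, mirroring why
#' narrow red-edge bands matter for telling visually similar tree crops
#' apart.
#'
#' @return A tibble with one row per class: `class_id`, `class_name`,
#'   list-columns `optical_mean` and `optical_sd` (named length-10
#'   vectors), `sar_mean` and `sar_sd` (named `VV`/`VH` vectors).
#' @export
lc_signatures <- function() {
  ob <- optical_bands()
  om <- rbind(
    oil_palm    = c(0.030, 0.060, 0.040, 0.100, 0.260, 0.300, 0.320, 0.340, 0.160, 0.070),
    rubber      = c(0.030, 0.062, 0.042, 0.130, 0.310, 0.360, 0.330, 0.350, 0.190, 0.080),
    other_trees = c(0.025, 0.050, 0.030, 0.080, 0.220, 0.270, 0.300, 0.310, 0.130, 0.050),
    shrub       = c(0.050, 0.080, 0.090, 0.150, 0.220, 0.250, 0.260, 0.270, 0.250, 0.150),
    bare        = c(0.110, 0.150, 0.190, 0.220, 0.240, 0.260, 0.280, 0.290, 0.380, 0.300),
    water       = c(0.060, 0.050, 0.030, 0.020, 0.015, 0.012, 0.010, 0.008, 0.004, 0.003)
  )
  colnames(om) <- ob
  sm <- rbind(
    oil_palm    = c(VV = -7.5,  VH = -13.0),
    rubber      = c(VV = -8.5,  VH = -14.5),
    other_trees = c(VV = -7.0,  VH = -12.0),
    shrub       = c(VV = -10.0, VH = -17.0),
    bare        = c(VV = -14.0, VH = -22.0),
    water       = c(VV = -20.0, VH = -28.0)
  )
  cls <- lc_classes()
  tibble(
    class_id = cls$class_id,
    class_name = cls$class_name,
    optical_mean = lapply(seq_len(6), function(i) om[i, ]),
    optical_sd = lapply(seq_len(6), function(i) {
      stats::setNames(rep(0.012, 10), ob)
    }),
    sar_mean = lapply(seq_len(6), function(i) sm[i, ]),
    sar_sd = lapply(seq_len(6), function(i) c(VV = 1.2, VH = 1.4))
  )
}

validate_signatures <- function(signatures, class_ids) {
  need <- c("class_id", "optical_mean", "optical_sd", "sar_mean", "sar_sd")
  miss <- setdiff(need, names(signatures))
  if (length(miss))
    stopf("signature table lacks column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(signatures$class_id))
    stopf("duplicate class_id in signature table")
  absent <- setdiff(class_ids, signatures$class_id)
  if (length(absent))
    stopf("no signature for class_id %s", paste(absent, collapse = ", "))
  for (i in seq_len(nrow(signatures))) {
    mu <- signatures$optical_mean[[i]]
    if (any(mu < 0 | mu > 1))
      stopf("optical means for class %d outside [0, 1]", signatures$class_id[i])
    if (any(signatures$optical_sd[[i]] < 0))
      stopf("negative optical sd for class %d", signatures$class_id[i])
  }
  invisible(signatures)
}
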