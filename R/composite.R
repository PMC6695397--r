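#' Cloud screening rule
#'
#' Per-scene cloud detection combines the delivered quality mask with
#' spectral tests on the screening bands: a pixel is cloudy if the QA
#' mask says so, or it is simultaneously bright in the blue (B2) and
#' short-wave infrared (B11) bands, or its cirrus band (when supplied)
#' exceeds the cirrus threshold. The thresholds are configuration with
#' these defaults; only the shape of the rule is fixed.
#'
#' @param blue_threshold,swir_threshold,cirrus_threshold Reflectance
#'   thresholds in `[0, 1]`.
#' @param nir_floor Minimum near-infrared (B8) reflectance for the
#'   blue/SWIR brightness test (0 disables the guard).
#' @return A `pc_cloud_rule` list.
#' @export
cloud_rule <- function(blue_threshold = 0.25, swir_threshold = 0.20,
                       cirrus_threshold = 0.01, nir_floor = 0) {
  vals <- c(blue_threshold, swir_threshold, cirrus_threshold, nir_floor)
  if (any(vals < 0 | vals > 1)) stopf("cloud thresholds must lie in [0, 1]")
  structure(list(blue_threshold = blue_threshold,
                 swir_threshold = swir_threshold,
                 cirrus_threshold = cirrus_threshold,
                 nir_floor = nir_floor),
            class = "pc_cloud_rule")
}

#' Detect clouds in a single-date scene
#'
#' @param bands A row x col x band array (or single-date `pc_raster`)
#'   containing at least the screening bands `B2`, `B8` and `B11`.
#' @param qa Optional logical matrix: the delivered cloud mask, which
#'   dominates (a QA-flagged pixel is always cloudy).
#' @param rule A [cloud_rule()].
#' @param cirrus Optional cirrus-band reflectance matrix; when supplied
#'   the cirrus test participates in the union.
#' @return A logical cloud matrix congruent with the scene.
#' @export
detect_clouds <- function(bands, qa = NULL, rule = cloud_rule(), cirrus = NULL) {
  if (inherits(bands, "pc_raster")) bands <- bands$values
  nms <- dimnames(bands)[[3]]
  for (b in c("B2", "B8", "B11")) {
    if (is.null(nms) || !b %in% nms)
      stopf("screening band '%s' is missing from the scene", b)
  }
  spectral <- bands[, , "B2"] > rule$blue_threshold &
    bands[, , "B11"] > rule$swir_threshold &
    bands[, , "B8"] >= rule$nir_floor
  out <- spectral
  if (!is.null(cirrus)) out <- out | (cirrus > rule$cirrus_threshold)
  if (!is.null(qa)) {
    if (!all(dim(qa) == dim(out)))
      stopf("`qa` mask dimensions do not match the scene")
    out <- out | qa
  }
  out
}

# percentile-window mean of each row of a pixels x dates matrix (NA =
# unusable observation); linear-interpolation ("type 7") percentiles,
# closed retention interval, nearest-to-median fallback when the
# interpolated interval captures no observation
pctl_window_mean <- function(vals, p_lo, p_hi, min_obs) {
  npx <- nrow(vals); nd <- ncol(vals)
  n <- rowSums(!is.na(vals))
  out <- rep(NA_real_, npx)
  usable <- which(n >= max(1L, min_obs))
  if (!length(usable)) return(list(value = out, n = n))
  v <- vals[usable, , drop = FALSE]
  nu <- n[usable]
  ord <- order(row(v), v, na.last = TRUE)
  s <- matrix(v[ord], nrow = length(usable), byrow = TRUE)
  q_at <- function(p) {
    h <- (nu - 1) * p / 100 + 1
    lo <- floor(h); hi <- ceiling(h)
    i <- seq_along(nu)
    s[cbind(i, lo)] + (h - lo) * (s[cbind(i, hi)] - s[cbind(i, lo)])
  }
  qlo <- q_at(p_lo); qhi <- q_at(p_hi)
  eps <- 1e-9 * pmax(1, abs(qlo), abs(qhi))
  inside <- !is.na(s) & s >= (qlo - eps) & s <= (qhi + eps)
  k <- rowSums(inside)
  sv <- s; sv[!inside] <- 0
  val <- rowSums(sv) / k
  none <- which(k == 0)
  if (length(none)) {
    med <- q_at(50)[none]
    dist <- abs(s[none, , drop = FALSE] - med)
    pick <- max.col(-ifelse(is.na(dist), Inf, dist), ties.method = "first")
    val[none] <- s[cbind(none, pick)]
  }
  out[usable] <- val
  list(value = out, n = n)
}

#' Percentile-window mean composite
#'
#' Reduces a multi-date optical stack to one image: per pixel and band,
#' the clear (cloud-free) observations are ranked, the `[p_lo, p_hi]`
#' percentile bounds are computed by linear interpolation, and all
#' observations inside the closed interval are averaged. The default
#' 40-60 window yields a robust around-the-median mean that rejects
#' residual cloud (bright) and shadow (dark) outliers. Pixels with fewer
#' than `min_obs` clear observations are missing; `valid_obs` records
#' the clear count everywhere.
#'
#' @param stack A `pc_scene_stack`.
#' @param cloud_masks Optional list of per-date logical cloud masks;
#'   defaults to the stack's QA masks.
#' @param p_lo,p_hi Percentile window bounds, `0 <= p_lo < p_hi <= 100`.
#' @param min_obs Minimum clear observations for a valid composite pixel.
#' @return A 10-band `pc_raster` with attribute `valid_obs` (integer
#'   matrix of clear counts).
#' @export
percentile_mean_composite <- function(stack, cloud_masks = NULL,
                                      p_lo = 40, p_hi = 60, min_obs = 3) {
  if (!inherits(stack, "pc_scene_stack")) stopf("`stack` must be a pc_scene_stack")
  nd <- length(stack$bands)
  if (nd < 1) stopf("empty stack: no dates to composite")
  if (!(p_lo >= 0 && p_lo < p_hi && p_hi <= 100))
    stopf("percentile window requires 0 <= p_lo < p_hi <= 100")
  d <- dim(stack$bands[[1]])
  nms <- dimnames(stack$bands[[1]])[[3]]
  npx <- d[1] * d[2]
  if (is.null(cloud_masks)) cloud_masks <- stack$qa
  if (length(cloud_masks) != nd) stopf("need one cloud mask per date")
  clear <- matrix(TRUE, npx, nd)
  for (t in seq_len(nd)) {
    m <- cloud_masks[[t]]
    if (!is.null(m)) clear[, t] <- !as.vector(m)
  }
  out <- array(NA_real_, dim = d, dimnames = list(NULL, NULL, nms))
  valid <- NULL
  for (b in seq_len(d[3])) {
    vals <- matrix(NA_real_, npx, nd)
    for (t in seq_len(nd)) {
      v <- as.vector(stack$bands[[t]][, , b])
      v[!clear[, t]] <- NA_real_
      vals[, t] <- v
    }
    r <- pctl_window_mean(vals, p_lo, p_hi, min_obs)
    out[, , b] <- matrix(r$value, d[1], d[2])
    if (is.null(valid)) valid <- matrix(as.integer(r$n), d[1], d[2])
  }
  comp <- pc_raster(out, res = stack$res, xmin = stack$xmin,
                    ymax = stack$ymax, crs = stack$crs)
  attr(comp, "valid_obs") <- valid
  comp
}

#' Clear-observation counts of a composite
#' @param composite Output of [percentile_mean_composite()].
#' @return Integer matrix of per-pixel clear observation counts.
#' @export
valid_obs <- function(composite) attr(composite, "valid_obs")

#' Temporal statistics of a radar stack
#'
#' Per-pixel temporal mean and population standard deviation (divide by
#' n) of the VV and VH backscatter series, in dB. A single-date stack
#' yields zero standard deviation.
#'
#' @param stack A `pc_sar_stack`.
#' @return A 4-band `pc_raster`: `VV_mean`, `VV_sd`, `VH_mean`, `VH_sd`.
#' @export
sar_temporal_stats <- function(stack) {
  if (!inherits(stack, "pc_sar_stack")) stopf("`stack` must be a pc_sar_stack")
  nd <- length(stack$vv)
  if (nd < 1) stopf("empty stack: no dates")
  d0 <- dim(stack$vv[[1]])
  for (t in seq_len(nd)) {
    if (!all(dim(stack$vv[[t]]) == d0) || !all(dim(stack$vh[[t]]) == d0))
      stopf("grid mismatch among dates in the radar stack")
  }
  chan_stats <- function(lst) {
    s1 <- Reduce(`+`, lst)
    s2 <- Reduce(`+`, lapply(lst, function(m) m * m))
    mu <- s1 / nd
    va <- pmax(s2 / nd - mu * mu, 0)
    list(mean = mu, sd = sqrt(va))
  }
  vv <- chan_stats(stack$vv); vh <- chan_stats(stack$vh)
  arr <- array(c(vv$mean, vv$sd, vh$mean, vh$sd),
               dim = c(d0, 4),
               dimnames = list(NULL, NULL,
                               c("VV_mean", "VV_sd", "VH_mean", "VH_sd")))
  pc_raster(arr, res = stack$res, xmin = stack$xmin, ymax = stack$ymax,
            crs = stack$crs)
}
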