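#' Synthetic landscapes and image time series
#'
#' The generator builds a patchy six-class landscape with known ground
#' truth, then renders multi-date optical and radar stacks from per-class
#' signatures, a smooth DEM and the vector layers (reference polygons and
#' concession/district/park zones) the downstream stages consume. All
#' functions are deterministic given `seed`.
#'
#' @name synth
NULL

# smoothed white noise on a torus (FFT convolution with a Gaussian kernel);
# consumes the current RNG stream
gaussian_field <- function(nr, nc, scale) {
  z <- matrix(rnorm(nr * nc), nr, nc)
  if (scale <= 0) return(z)
  dr <- 0:(nr - 1); dr <- pmin(dr, nr - dr)
  dc <- 0:(nc - 1); dc <- pmin(dc, nc - dc)
  k <- outer(stats::dnorm(dr, sd = scale), stats::dnorm(dc, sd = scale))
  k <- k / sum(k)
  Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE)) / (nr * nc)
}

# smoothed field standardised to zero mean, unit sd
gaussian_field_unit <- function(nr, nc, scale) {
  f <- gaussian_field(nr, nc, scale)
  (f - mean(f)) / sd(f)
}

#' Generate a patchy ground-truth class map
#'
#' Thresholds a Gaussian-smoothed random field at the empirical quantiles
#' of the cumulative class weights, producing contiguous single-class
#' patches (plantation-block-like) whose empirical frequencies match the
#' requested weights to within one pixel's worth of ties.
#'
#' @param width,height Raster size in pixels (> 0).
#' @param class_weights Non-negative class proportions (normalised
#'   internally); length defines the number of classes.
#' @param patch_scale Gaussian smoothing radius in pixels (>= 1); larger
#'   values give larger patches.
#' @param seed Integer RNG seed.
#' @param res Cell size in metres.
#' @param block Integer block alignment (>= 1): the class field is drawn
#'   on a grid coarsened by this factor and expanded, so patch
#'   boundaries land on block edges. [simulate_scene()] uses the
#'   native-to-analysis resolution ratio (2), which makes every analysis
#'   cell single-class: ground truth and reference purity are then exact
#'   at the analysis resolution (mixed boundary pixels are deliberately
#'   not modelled).
#' @return A `pc_raster` whose values are integer class codes.
#' @export
generate_class_map <- function(width, height, class_weights,
                               patch_scale = 16, seed = 1, res = 10,
                               block = 1) {
  if (width < 1 || height < 1) stopf("raster size must be positive")
  if (any(!is.finite(class_weights)) || any(class_weights < 0) ||
      sum(class_weights) <= 0)
    stopf("`class_weights` must be non-negative and sum to a positive value")
  if (patch_scale < 1) stopf("`patch_scale` must be >= 1")
  block <- as.integer(block)
  if (block < 1) stopf("`block` must be >= 1")
  w <- class_weights / sum(class_weights)
  k <- length(w)
  set.seed(seed)
  hh <- ceiling(height / block); ww <- ceiling(width / block)
  f <- gaussian_field(hh, ww, patch_scale / block)
  pos <- which(w > 0)
  if (length(pos) == 1L) {
    cls <- matrix(pos, hh, ww)
  } else {
    wp <- w[pos]
    breaks <- quantile(f, cumsum(wp)[-length(pos)], names = FALSE, type = 7)
    idx <- findInterval(f, breaks, left.open = TRUE) + 1L
    cls <- matrix(pos[idx], hh, ww)
  }
  if (block > 1L) {
    cls <- cls[rep(seq_len(hh), each = block), rep(seq_len(ww), each = block),
               drop = FALSE][seq_len(height), seq_len(width), drop = FALSE]
  }
  pc_raster(cls, res = res)
}

# class-indexed lookup: per-pixel value of a per-class parameter
class_image <- function(cls, per_class) {
  matrix(per_class[cls], nrow(cls), ncol(cls))
}

#' Most-confusable partner class
#'
#' The fixed mapping of each class to the class it is most easily
#' mistaken for on the ground: the two target tree crops for each other,
#' other trees for rubber (forests vs tree plantations), shrub for other
#' trees, bare for shrub, and water for bare (turbid shallows vs wet
#' soil). The stand-condition drift of the scene generator moves pixel
#' signatures along these directions.
#'
#' @return Integer vector: `partner[class_id]`.
#' @export
confusion_partners <- function() {
  c(oil_palm = 2L, rubber = 1L, other_trees = 2L, shrub = 3L,
    bare = 4L, water = 5L)
}

#' Default per-class stand-condition drift amplitudes
#'
#' 1-sigma drift of each class toward its confusable partner, as a
#' fraction of the signature difference. The tree crops drift most (old
#' and defoliated stands), the broad vegetation classes moderately, and
#' the physically distinct classes need a larger relative drift for
#' their rare edge cases (turbid shallows, wet soil, sparse regrowth)
#' to register at all. Chosen so classification accuracy on held-out
#' reference pixels lands in the realistic band reported for this kind
#' of landscape (per-class accuracies roughly 80-97%).
#'
#' @return Named numeric vector indexed by class_id.
#' @export
default_confusion_amp <- function() {
  c(oil_palm = 0.45, rubber = 0.45, other_trees = 0.40, shrub = 0.40,
    bare = 0.60, water = 0.70)
}

sig_matrix <- function(signatures, col, names_expected) {
  s <- signatures[order(signatures$class_id), ]
  m <- do.call(rbind, s[[col]])
  rownames(m) <- s$class_id
  m
}

#' Generate a multi-date optical scene stack
#'
#' Renders each date as the per-class optical signature plus Gaussian
#' noise, then plants contiguous cloud blobs covering `cloud_fraction`
#' of the pixels per date: cloudy pixels are overwritten with bright
#' cloud reflectance and flagged in the per-date quality mask.
#'
#' @param truth A `pc_raster` ground-truth class map.
#' @param signatures Signature tibble (see [lc_signatures()]).
#' @param n_dates Number of acquisition dates.
#' @param cloud_fraction Per-date cloudy pixel share in `[0, 1]`.
#' @param seed Integer RNG seed.
#' @param cloud_scale Blob smoothness (pixels) for the cloud fields.
#' @param cloud_reflectance Length-10 reflectance written under clouds.
#' @param persistent_brightness,persistent_vigour Relative (1-sigma)
#'   amplitudes of two smooth condition fields, stable across dates,
#'   that modulate each pixel's spectrum: a brightness field scaling all
#'   bands, and a canopy-vigour field raising the near-infrared/red-edge
#'   plateau while slightly lowering the red and short-wave infrared.
#'   They emulate real within-class variability (stand age, density,
#'   moisture) that temporal compositing cannot average away and that
#'   makes spectrally adjacent classes genuinely confusable; set both to
#'   0 for the idealised noiseless limit.
#' @param persistent_scale Correlation length (pixels) of the condition
#'   fields.
#' @param confusion_amp 1-sigma amplitude of the stand-condition drift:
#'   each pixel's signature moves `confusion_amp * g` of the way toward
#'   its most-confusable partner class (see [confusion_partners()]),
#'   where `g` is a smooth unit field. This is what makes held-out
#'   reference pixels genuinely misclassifiable (old or defoliated
#'   stands resembling the neighbouring crop); 0 disables it.
#' @param confusion_field Optional pre-drawn unit field so that the
#'   optical and radar series share one stand-condition realisation (as
#'   [simulate_scene()] arranges); drawn internally when `NULL`.
#' @return A `pc_scene_stack`: list with `dates`, `bands` (per-date
#'   row x col x 10 arrays), `qa` (per-date logical cloud masks) and the
#'   grid metadata of `truth`.
#' @export
generate_optical_series <- function(truth, signatures = lc_signatures(),
                                    n_dates = 8, cloud_fraction = 0.3,
                                    seed = 1, cloud_scale = 24,
                                    cloud_reflectance = NULL,
                                    persistent_brightness = 0.06,
                                    persistent_vigour = 0.12,
                                    persistent_scale = 1.2,
                                    confusion_amp = NULL,
                                    confusion_field = NULL) {
  cls <- truth$values
  validate_signatures(signatures, sort(unique(as.vector(cls))))
  if (cloud_fraction < 0 || cloud_fraction > 1)
    stopf("`cloud_fraction` must be in [0, 1]")
  if (n_dates < 1) stopf("`n_dates` must be >= 1")
  ob <- optical_bands()
  mu <- sig_matrix(signatures, "optical_mean")
  sg <- sig_matrix(signatures, "optical_sd")
  if (is.null(cloud_reflectance))
    cloud_reflectance <- stats::setNames(c(rep(0.55, 8), 0.45, 0.35), ob)
  nr <- nrow(cls); nc <- ncol(cls); npx <- nr * nc
  set.seed(seed)
  # date-stable condition fields (drawn once per series)
  g_bright <- gaussian_field_unit(nr, nc, persistent_scale)
  g_vigour <- gaussian_field_unit(nr, nc, persistent_scale)
  if (is.null(confusion_field))
    confusion_field <- gaussian_field_unit(nr, nc, persistent_scale)
  confusion_amp <- confusion_amp %||% default_confusion_amp()
  if (length(confusion_amp) == 1L) confusion_amp <- rep(confusion_amp, nrow(mu))
  drift <- class_image(cls, confusion_amp) * confusion_field
  partner <- confusion_partners()
  vig_up <- c("B5", "B6", "B7", "B8", "B8A")     # canopy plateau
  vig_dn <- c("B4", "B11", "B12")                # red / SWIR absorption
  base <- array(NA_real_, dim = c(nr, nc, length(ob)),
                dimnames = list(NULL, NULL, ob))
  for (b in seq_along(ob)) {
    m <- class_image(cls, mu[, b])
    if (any(confusion_amp > 0))
      m <- m + drift * (class_image(cls, mu[partner, b]) - m)
    m <- m * (1 + persistent_brightness * g_bright)
    if (ob[b] %in% vig_up) m <- m * (1 + persistent_vigour * g_vigour)
    if (ob[b] %in% vig_dn) m <- m * (1 - 0.5 * persistent_vigour * g_vigour)
    base[, , b] <- m
  }
  bands <- vector("list", n_dates)
  qa <- vector("list", n_dates)
  for (d in seq_len(n_dates)) {
    arr <- base
    for (b in seq_along(ob)) {
      s <- class_image(cls, sg[, b])
      arr[, , b] <- arr[, , b] + matrix(rnorm(npx), nr, nc) * s
    }
    if (cloud_fraction >= 1) {
      mask <- matrix(TRUE, nr, nc)
    } else if (cloud_fraction <= 0) {
      mask <- matrix(FALSE, nr, nc)
    } else {
      f <- gaussian_field(nr, nc, cloud_scale)
      kcl <- round(cloud_fraction * npx)
      thr <- -sort(-f, partial = kcl)[kcl]
      mask <- f >= thr
    }
    if (any(mask)) {
      nm <- sum(mask)
      for (b in seq_along(ob)) {
        pl <- arr[, , b]
        pl[mask] <- cloud_reflectance[b] + rnorm(nm, sd = 0.02)
        arr[, , b] <- pl
      }
    }
    arr[arr < 0] <- 0          # reflectance is physically non-negative
    bands[[d]] <- arr
    qa[[d]] <- mask
  }
  structure(list(dates = seq_len(n_dates), bands = bands, qa = qa,
                 res = truth$res, xmin = truth$xmin, ymax = truth$ymax,
                 crs = truth$crs),
            class = "pc_scene_stack")
}

#' Generate a multi-date radar (VV/VH) stack
#'
#' Backscatter is rendered as the class signature mean plus multiplicative
#' gamma speckle applied in linear power and log-standardised so the
#' dB-domain mean and standard deviation equal the signature parameters
#' exactly (a raw multi-look gamma speckle would bias the dB mean by
#' `10/ln 10 * (digamma(L) - log L)`).
#'
#' @inheritParams generate_optical_series
#' @param looks Equivalent number of speckle looks (shape of the gamma
#'   multiplier).
#' @param persistent_sd Standard deviation (dB) of a smooth, date-stable
#'   backscatter texture field shared by both polarisations (structural
#'   within-class variability that temporal averaging keeps); 0 disables
#'   it.
#' @return A `pc_sar_stack`: list with `dates`, `vv`, `vh` (per-date dB
#'   matrices) and grid metadata.
#' @export
generate_sar_series <- function(truth, signatures = lc_signatures(),
                                n_dates = 12, seed = 1, looks = 5,
                                persistent_sd = 0.8,
                                persistent_scale = 1.2,
                                confusion_amp = NULL,
                                confusion_field = NULL) {
  cls <- truth$values
  validate_signatures(signatures, sort(unique(as.vector(cls))))
  if (n_dates < 1) stopf("`n_dates` must be >= 1")
  mu <- sig_matrix(signatures, "sar_mean")
  sg <- sig_matrix(signatures, "sar_sd")
  nr <- nrow(cls); nc <- ncol(cls); npx <- nr * nc
  ctr <- digamma(looks) - log(looks)
  scl <- sqrt(trigamma(looks))
  set.seed(seed)
  tex <- if (persistent_sd > 0)
    persistent_sd * gaussian_field_unit(nr, nc, persistent_scale)
  else matrix(0, nr, nc)
  if (is.null(confusion_field))
    confusion_field <- gaussian_field_unit(nr, nc, persistent_scale)
  confusion_amp <- confusion_amp %||% default_confusion_amp()
  if (length(confusion_amp) == 1L) confusion_amp <- rep(confusion_amp, nrow(mu))
  drift <- class_image(cls, confusion_amp) * confusion_field
  partner <- confusion_partners()
  speckle_z <- function() {
    g <- rgamma(npx, shape = looks, rate = looks)
    matrix((log(g) - ctr) / scl, nr, nc)
  }
  mvv <- class_image(cls, mu[, "VV"])
  mvh <- class_image(cls, mu[, "VH"])
  if (any(confusion_amp > 0)) {
    mvv <- mvv + drift * (class_image(cls, mu[partner, "VV"]) - mvv)
    mvh <- mvh + drift * (class_image(cls, mu[partner, "VH"]) - mvh)
  }
  mvv <- mvv + tex
  mvh <- mvh + tex
  vv <- vh <- vector("list", n_dates)
  for (d in seq_len(n_dates)) {
    vv[[d]] <- mvv + class_image(cls, sg[, "VV"]) * speckle_z()
    vh[[d]] <- mvh + class_image(cls, sg[, "VH"]) * speckle_z()
  }
  structure(list(dates = seq_len(n_dates), vv = vv, vh = vh,
                 res = truth$res, xmin = truth$xmin, ymax = truth$ymax,
                 crs = truth$crs),
            class = "pc_sar_stack")
}

#' Generate DEM, zone polygons and labelled reference polygons
#'
#' The DEM is a sum of low-frequency cosine surfaces on its own coarser
#' grid. Zones are rectangles: `n_concessions` randomly placed (possibly
#' overlapping) concessions, two districts that partition the extent, and
#' one park. Reference polygons are squares placed entirely inside
#' single-class patches with a margin of at least one analysis cell, so
#' every pixel they cover has exactly one true class.
#'
#' @param truth A `pc_raster` ground-truth class map.
#' @param n_concessions Number of concession rectangles (>= 1).
#' @param n_reference_polygons_per_class Reference polygons per class (>= 1).
#' @param seed Integer RNG seed.
#' @param dem `"hilly"` (cosine hills) or `"flat"`.
#' @param dem_res DEM cell size in metres.
#' @param ref_poly_size Side of the square reference polygons, metres
#'   (snapped to an odd number of analysis cells).
#' @param margin_m Extra pure margin around each reference polygon,
#'   metres (default 0: polygons may reach patch edges, so the samples
#'   also represent near-boundary stands).
#' @param analysis_res Analysis cell size, metres; polygons are aligned
#'   to this grid so every covered analysis cell is single-class.
#' @param relief Peak-to-trough amplitude scale of the hilly DEM, metres.
#' @return A list with `dem` (a `pc_raster`), `zones` and
#'   `reference_polygons` (polygon tibbles).
#' @export
generate_ancillary <- function(truth, n_concessions = 4,
                               n_reference_polygons_per_class = 5,
                               seed = 1, dem = c("hilly", "flat"),
                               dem_res = 30, ref_poly_size = 100,
                               margin_m = 0, analysis_res = 20,
                               relief = 250) {
  dem <- match.arg(dem)
  if (n_concessions < 1 || any(n_reference_polygons_per_class < 1))
    stopf("polygon counts must be >= 1")
  cls <- truth$values
  res <- truth$res
  W <- ncol(cls) * res; H <- nrow(cls) * res
  set.seed(seed)

  # --- DEM ---
  nrd <- ceiling(H / dem_res); ncd <- ceiling(W / dem_res)
  if (dem == "flat") {
    z <- matrix(100, nrd, ncd)
  } else {
    xs <- (seq_len(ncd) - 0.5) * dem_res
    ys <- (nrd - seq_len(nrd) + 0.5) * dem_res
    z <- matrix(100, nrd, ncd)
    for (k in 1:4) {
      wl <- runif(1, 0.4, 1.5) * max(W, H)   # wavelength, metres
      th <- runif(1, 0, 2 * pi)              # direction
      ph <- runif(1, 0, 2 * pi)
      amp <- relief / k
      proj <- outer(ys * sin(th), xs * cos(th), `+`)
      z <- z + amp * cos(2 * pi * proj / wl + ph)
    }
  }
  dem_r <- pc_raster(z, res = dem_res, xmin = truth$xmin, ymax = truth$ymax,
                     crs = truth$crs)

  # --- zones ---
  zone_rows <- list()
  for (i in seq_len(n_concessions)) {
    zw <- runif(1, 0.20, 0.45) * W; zh <- runif(1, 0.20, 0.45) * H
    x0 <- runif(1, 0, W - zw); y0 <- runif(1, 0, H - zh)
    zone_rows[[length(zone_rows) + 1]] <-
      list(zone_id = sprintf("concession_%02d", i), kind = "concession",
           geometry = list(rect_ring(x0, y0, x0 + zw, y0 + zh)))
  }
  zone_rows[[length(zone_rows) + 1]] <-
    list(zone_id = "district_west", kind = "district",
         geometry = list(rect_ring(0, 0, W / 2, H)))
  zone_rows[[length(zone_rows) + 1]] <-
    list(zone_id = "district_east", kind = "district",
         geometry = list(rect_ring(W / 2, 0, W, H)))
  pw <- 0.30 * W; ph <- 0.30 * H
  px0 <- runif(1, 0, W - pw); py0 <- runif(1, 0, H - ph)
  zone_rows[[length(zone_rows) + 1]] <-
    list(zone_id = "park_01", kind = "park",
         geometry = list(rect_ring(px0, py0, px0 + pw, py0 + ph)))
  zones <- bind_rows(lapply(zone_rows, function(r) {
    tb <- tibble(zone_id = r$zone_id, kind = r$kind)
    tb$geometry <- r$geometry
    tb
  }))

  # --- reference polygons (aligned to the analysis grid) ---
  fact <- max(1L, round(analysis_res / res))
  nra <- nrow(cls) %/% fact; nca <- ncol(cls) %/% fact
  sp <- max(1L, round(ref_poly_size / analysis_res))   # side, analysis cells
  if (sp %% 2L == 0L) sp <- sp + 1L
  mg <- ceiling(margin_m / analysis_res)
  k <- sp + 2L * mg                                    # odd scan window
  classes <- sort(unique(as.vector(cls)))
  n_per_class <- n_reference_polygons_per_class
  if (length(n_per_class) == 1L) n_per_class <- rep(n_per_class, max(classes))
  cn <- lc_classes()
  ref_rows <- list(); pid <- 0L
  for (cc in classes) {
    n_want <- n_per_class[cc]
    # analysis cells wholly of class cc
    pure <- block_aggregate((cls[seq_len(nra * fact), seq_len(nca * fact)] == cc) * 1,
                            fact)
    ws <- window_sums((pure == 1) * 1, k)
    cand <- which(ws$sum == k * k)                      # fully pure k x k block
    nm <- cn$class_name[match(cc, cn$class_id)]
    if (length(cand) < 1)
      stopf(paste0("cannot place a reference polygon for class '", nm,
                   "': landscape too fragmented at this patch scale"),
            class = "palmcover_placement_error")
    cand <- sample(cand)
    chosen <- integer(0)
    for (idx in cand) {                                 # greedy spacing
      r0 <- (idx - 1L) %% nra + 1L
      c0 <- (idx - 1L) %/% nra + 1L
      if (length(chosen)) {
        rr <- (chosen - 1L) %% nra + 1L
        ccol <- (chosen - 1L) %/% nra + 1L
        # keep at least one free cell between plots: train and test
        # samples then do not share stand-condition microstructure
        if (any(pmax(abs(rr - r0), abs(ccol - c0)) < sp + 1L)) next
      }
      chosen <- c(chosen, idx)
      if (length(chosen) == n_want) break
    }
    if (length(chosen) < n_want)
      chosen <- c(chosen,
                  setdiff(cand, chosen)[seq_len(n_want - length(chosen))])
    if (anyNA(chosen) || length(chosen) < n_want)
      stopf(paste0("cannot place ", n_want,
                   " reference polygons for class '", nm, "'"),
            class = "palmcover_placement_error")
    half <- sp * analysis_res / 2
    for (idx in chosen) {
      r0 <- (idx - 1L) %% nra + 1L
      c0 <- (idx - 1L) %/% nra + 1L
      xc <- truth$xmin + (c0 - 0.5) * analysis_res
      yc <- truth$ymax - (r0 - 0.5) * analysis_res
      pid <- pid + 1L
      ref_rows[[pid]] <- list(polygon_id = pid, class_id = cc,
                              geometry = list(rect_ring(xc - half, yc - half,
                                                        xc + half, yc + half)))
    }
  }
  reference_polygons <- bind_rows(lapply(ref_rows, function(r) {
    tb <- tibble(polygon_id = r$polygon_id, class_id = r$class_id)
    tb$geometry <- r$geometry
    tb
  }))
  list(dem = dem_r, zones = zones, reference_polygons = reference_polygons)
}

#' Simulate a complete scene bundle
#'
#' Convenience wrapper that draws a ground-truth landscape and everything
#' the pipeline needs from it: an optical time series with cloud blobs, a
#' radar time series with speckle, a DEM and the vector layers. The
#' defaults define the package's standard synthetic study conditions
#' (256 x 256 pixels at 10 m, 8 optical and 12 radar dates, 30% clouds
#' per date).
#'
#' @param size Landscape side length in pixels (10 m native grid).
#' @param n_optical,n_sar Number of optical / radar dates.
#' @param cloud_fraction Per-date cloudy share.
#' @param patch_scale Landscape patch smoothness, pixels.
#' @param class_weights Six class proportions.
#' @param n_concessions Number of concession rectangles.
#' @param n_reference_polygons_per_class Reference plots per class; the
#'   default (`NULL`) allocates `n_reference_plots` proportionally to
#'   the class weights (floor 48), so the per-cell inclusion rate is
#'   uniform across classes and the reference sample behaves like a
#'   stratified probability sample of the landscape.
#' @param n_reference_plots Total reference plots under proportional
#'   allocation.
#' @param ref_poly_size Reference plot side, metres (default 20: one
#'   analysis cell per plot).
#' @param signatures Signature tibble.
#' @param dem `"hilly"` or `"flat"`.
#' @param seed Master seed; stage seeds are drawn from it.
#' @param res Native cell size, metres.
#' @param ... Passed to [generate_ancillary()] (e.g. `ref_poly_size`,
#'   `margin_m` for smaller scenes).
#' @return A list of class `pc_scene` with elements `truth`, `optical`,
#'   `sar`, `dem`, `zones`, `reference_polygons`, `signatures`, `params`.
#' @export
simulate_scene <- function(size = 256, n_optical = 8, n_sar = 12,
                           cloud_fraction = 0.3, patch_scale = 32,
                           class_weights = c(0.12, 0.15, 0.40, 0.18, 0.09, 0.06),
                           n_concessions = 4,
                           n_reference_polygons_per_class = NULL,
                           n_reference_plots = 1200,
                           ref_poly_size = 20,
                           signatures = lc_signatures(),
                           dem = "hilly", seed = 1, res = 10, ...) {
  if (is.null(n_reference_polygons_per_class))
    n_reference_polygons_per_class <-
      pmax(48, round(n_reference_plots * class_weights / sum(class_weights)))
  set.seed(seed)
  seeds <- sample.int(2^31 - 2, 5)
  truth <- generate_class_map(size, size, class_weights,
                              patch_scale = patch_scale, seed = seeds[1],
                              res = res, block = 2)
  # one stand-condition realisation shared by the optical and radar series
  set.seed(seeds[5])
  g_confuse <- gaussian_field_unit(size, size, 1.2)
  optical <- generate_optical_series(truth, signatures, n_dates = n_optical,
                                     cloud_fraction = cloud_fraction,
                                     seed = seeds[2],
                                     confusion_field = g_confuse)
  sar <- generate_sar_series(truth, signatures, n_dates = n_sar,
                             seed = seeds[3], confusion_field = g_confuse)
  anc <- generate_ancillary(truth, n_concessions = n_concessions,
                            n_reference_polygons_per_class =
                              n_reference_polygons_per_class,
                            ref_poly_size = ref_poly_size,
                            seed = seeds[4], dem = dem, ...)
  structure(list(truth = truth, optical = optical, sar = sar,
                 dem = anc$dem, zones = anc$zones,
                 reference_polygons = anc$reference_polygons,
                 signatures = signatures,
                 params = list(size = size, n_optical = n_optical,
                               n_sar = n_sar, cloud_fraction = cloud_fraction,
                               patch_scale = patch_scale,
                               class_weights = class_weights, seed = seed,
                               res = res)),
            class = "pc_scene")
}

#' Write a scene bundle to disk
#'
#' Emits the complete bundle under `dir`: ground truth, per-date optical
#' bands + QA mask and radar channels as TIFF with JSON sidecars, the DEM,
#' and the vector layers as GeoJSON.
#'
#' @param scene A `pc_scene` from [simulate_scene()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene_bundle <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_raster_tiff(scene$truth, file.path(dir, "truth.tif"))
  write_raster_tiff(scene$dem, file.path(dir, "dem.tif"))
  for (d in scene$optical$dates) {
    arr <- scene$optical$bands[[d]]
    qa <- scene$optical$qa[[d]] * 1
    full <- array(c(arr, qa), dim = c(dim(arr)[1:2], dim(arr)[3] + 1),
                  dimnames = list(NULL, NULL, c(dimnames(arr)[[3]], "QA")))
    write_raster_tiff(pc_raster(full, res = scene$optical$res,
                                xmin = scene$optical$xmin,
                                ymax = scene$optical$ymax),
                      file.path(dir, sprintf("optical_%02d.tif", d)))
  }
  for (d in scene$sar$dates) {
    arr <- array(c(scene$sar$vv[[d]], scene$sar$vh[[d]]),
                 dim = c(dim(scene$sar$vv[[d]]), 2),
                 dimnames = list(NULL, NULL, c("VV", "VH")))
    write_raster_tiff(pc_raster(arr, res = scene$sar$res,
                                xmin = scene$sar$xmin, ymax = scene$sar$ymax),
                      file.path(dir, sprintf("sar_%02d.tif", d)))
  }
  write_polygons_geojson(scene$zones, file.path(dir, "zones.geojson"))
  write_polygons_geojson(scene$reference_polygons,
                         file.path(dir, "reference_polygons.geojson"))
  invisible(dir)
}

#' Modal (majority) block aggregation of a class map
#'
#' Aggregates an integer class raster by an integer factor, assigning each
#' output cell the most frequent class among its input cells (ties break
#' to the smallest class code). Used to define ground truth on the 20 m
#' analysis grid from the 10 m native truth.
#'
#' @param map A `pc_raster` integer class map.
#' @param fact Integer aggregation factor.
#' @return A `pc_raster` class map at `res * fact`.
#' @export
aggregate_modal <- function(map, fact) {
  cls <- map$values
  ids <- sort(unique(as.vector(cls[!is.na(cls)])))
  best <- NULL; best_n <- NULL
  for (cc in ids) {
    cnt <- block_aggregate((cls == cc) * 1, fact) # mean of indicator
    if (is.null(best)) {
      best <- matrix(cc, nrow(cnt), ncol(cnt)); best_n <- cnt
    } else {
      take <- !is.na(cnt) & (is.na(best_n) | cnt > best_n)
      best[take] <- cc; best_n[take] <- cnt[take]
    }
  }
  pc_raster(best, res = map$res * fact, xmin = map$xmin, ymax = map$ymax,
            crs = map$crs)
}
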