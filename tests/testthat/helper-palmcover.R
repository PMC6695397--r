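# Shared fixtures and independent brute-force oracles.

# small scene for fast end-to-end style tests (96 px, fewer dates)
make_small_scene <- function(seed = 3, ...) {
  simulate_scene(size = 96, n_optical = 6, n_sar = 8, patch_scale = 12,
                 n_reference_plots = 400, seed = seed, ...)
}

# ray-casting point-in-polygon, written independently of the package's
# mgcv-based test (even-odd rule)
oracle_point_in_polygon <- function(px, py, ring) {
  n <- nrow(ring)
  if (all(ring[1, ] == ring[n, ])) { ring <- ring[-n, , drop = FALSE]; n <- n - 1 }
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi) inside <- !inside
    j <- i
  }
  inside
}

# brute-force percentile-window mean of one series: sort, interpolate the
# two percentile bounds, keep the closed interval, average; nearest to the
# median if the interval is empty
oracle_pctl_mean <- function(x, p_lo, p_hi) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0) return(NA_real_)
  s <- sort(x)
  qq <- function(p) {
    h <- (n - 1) * p / 100 + 1
    s[floor(h)] + (h - floor(h)) * (s[ceiling(h)] - s[floor(h)])
  }
  lo <- qq(p_lo); hi <- qq(p_hi)
  eps <- 1e-9 * max(1, abs(lo), abs(hi))
  keep <- s >= lo - eps & s <= hi + eps
  if (!any(keep)) return(s[which.min(abs(s - qq(50)))])
  mean(s[keep])
}

# brute-force windowed population SD with edge shrinkage and NA exclusion
oracle_moving_sd <- function(m, window) {
  h <- (window - 1) / 2
  out <- matrix(NA_real_, nrow(m), ncol(m))
  for (r in seq_len(nrow(m))) for (cc in seq_len(ncol(m))) {
    rs <- max(1, r - h):min(nrow(m), r + h)
    cs <- max(1, cc - h):min(ncol(m), cc + h)
    v <- as.vector(m[rs, cs]); v <- v[!is.na(v)]
    if (length(v)) out[r, cc] <- sqrt(mean((v - mean(v))^2))
  }
  out
}

# independent arithmetic for the stratified error-adjusted estimator
oracle_adjusted_areas <- function(counts, N, pixel_area, z = 1.96) {
  W <- N / sum(N)
  ns <- rowSums(counts)
  A <- sum(N) * pixel_area
  k <- nrow(counts)
  p <- matrix(0, k, k)
  for (i in seq_len(k)) if (ns[i] > 0) p[i, ] <- counts[i, ] / ns[i]
  pj <- rep(0, k); se <- rep(0, k)
  for (j in seq_len(k)) {
    for (i in seq_len(k)) pj[j] <- pj[j] + W[i] * p[i, j]
    v <- 0
    for (i in seq_len(k)) if (ns[i] > 1)
      v <- v + W[i]^2 * p[i, j] * (1 - p[i, j]) / (ns[i] - 1)
    se[j] <- sqrt(v)
  }
  list(area = pj * A, se = se * A,
       lo = (pj - z * se) * A, hi = (pj + z * se) * A)
}
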