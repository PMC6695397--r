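#' Error (confusion) matrix against a class map
#'
#' Cross-tabulates held-out test samples against the filtered class map:
#' entry `n[i, j]` counts test pixels mapped as class `i` whose reference
#' label is class `j` (rows = map, columns = reference — serialised with
#' explicit axis labels to prevent transposition bugs). The object also
#' records each class's mapped pixel total from the full map, needed by
#' the error-adjusted area estimator.
#'
#' @param test_samples Tibble with `row`, `col` and reference `class_id`
#'   (usually `role == "test"` rows from [split_reference()]).
#' @param map A `pc_raster` class map (after filtering).
#' @param pixel_area Area of one map pixel in hectares (0.04 ha for a
#'   20 m grid).
#' @return A `pc_error_matrix`: list with `counts` (K x K), `mapped_pixels`
#'   (length K), `pixel_area`, `classes`, and `n_excluded` (test pixels
#'   falling on missing map cells, dropped with a message).
#' @export
error_matrix <- function(test_samples, map, pixel_area) {
  cn <- lc_classes()
  k <- nrow(cn)
  mapped <- map$values[cbind(test_samples$row, test_samples$col)]
  drop <- is.na(mapped)
  if (any(drop))
    inform(sprintf("excluded %d test pixel(s) on missing map cells", sum(drop)))
  counts <- table(factor(mapped[!drop], levels = cn$class_id),
                  factor(test_samples$class_id[!drop], levels = cn$class_id))
  counts <- matrix(as.integer(counts), k, k,
                   dimnames = list(map = cn$class_name,
                                   reference = cn$class_name))
  mp <- tabulate(map$values[!is.na(map$values)], nbins = k)
  error_matrix_from_counts(counts, mp, pixel_area, n_excluded = sum(drop))
}

#' Build an error matrix from explicit counts
#'
#' Constructor for worked examples and externally tabulated matrices.
#'
#' @param counts K x K integer matrix, rows = mapped class, columns =
#'   reference class.
#' @param mapped_pixels Length-K mapped pixel totals per class.
#' @param pixel_area Pixel area in hectares.
#' @param class_names Optional class names (defaults to the six standard
#'   classes when K = 6, else `class_1..K`).
#' @param n_excluded Bookkeeping: test pixels excluded upstream.
#' @return A `pc_error_matrix`.
#' @export
error_matrix_from_counts <- function(counts, mapped_pixels, pixel_area,
                                     class_names = NULL, n_excluded = 0L) {
  counts <- as.matrix(counts)
  k <- nrow(counts)
  if (ncol(counts) != k) stopf("`counts` must be square")
  if (any(counts < 0)) stopf("confusion counts must be non-negative")
  if (length(mapped_pixels) != k)
    stopf("`mapped_pixels` must have one total per class")
  if (any(mapped_pixels < 0)) stopf("mapped pixel totals must be >= 0")
  if (is.null(class_names))
    class_names <- if (k == 6) lc_classes()$class_name else paste0("class_", seq_len(k))
  dimnames(counts) <- list(map = class_names, reference = class_names)
  structure(list(counts = counts, mapped_pixels = as.numeric(mapped_pixels),
                 pixel_area = pixel_area, classes = class_names,
                 n_excluded = as.integer(n_excluded)),
            class = "pc_error_matrix")
}

#' @export
print.pc_error_matrix <- function(x, ...) {
  cat(sprintf("<pc_error_matrix> %d classes, %d test pixels, %.3g ha/pixel\n",
              nrow(x$counts), sum(x$counts), x$pixel_area))
  print(x$counts)
  invisible(x)
}

#' Accuracy metrics from an error matrix
#'
#' Sample-count overall accuracy, per-class user's accuracy (UA,
#' `n_ii / n_i.` — 1 minus commission error) and producer's accuracy
#' (PA, `n_jj / n_.j` — 1 minus omission error), plus the area-weighted
#' overall accuracy `sum_i W_i n_ii / n_i.` that weights each mapped
#' stratum by its mapped-area share. Classes with an empty row or column
#' get `NA` (metric undefined), never zero.
#'
#' @param m A `pc_error_matrix`.
#' @return A list: `overall`, `overall_area_weighted`, and `per_class`
#'   (tibble with `class_id`, `class_name`, `n_map`, `n_ref`, `ua`, `pa`).
#' @export
accuracy_metrics <- function(m) {
  cm <- m$counts
  tot <- sum(cm)
  if (tot == 0) stopf("error matrix holds no test samples")
  rs <- rowSums(cm); cs <- colSums(cm); dg <- diag(cm)
  ua <- ifelse(rs > 0, dg / rs, NA_real_)
  pa <- ifelse(cs > 0, dg / cs, NA_real_)
  w <- m$mapped_pixels / sum(m$mapped_pixels)
  oa_w <- sum(w[rs > 0] * (dg / rs)[rs > 0])
  list(
    overall = sum(dg) / tot,
    overall_area_weighted = oa_w,
    per_class = tibble(class_id = seq_along(ua),
                       class_name = m$classes,
                       n_map = as.integer(rs), n_ref = as.integer(cs),
                       ua = as.numeric(ua), pa = as.numeric(pa))
  )
}

#' @export
tidy.pc_error_matrix <- function(x, ...) accuracy_metrics(x)$per_class

#' @export
glance.pc_error_matrix <- function(x, ...) {
  a <- accuracy_metrics(x)
  tibble(overall = a$overall,
         overall_area_weighted = a$overall_area_weighted,
         n_test = sum(x$counts), n_excluded = x$n_excluded)
}

#' Stratified error-adjusted area estimation
#'
#' The standard stratified estimator that corrects mapped pixel-count
#' areas for classification bias using the reference sample. With
#' stratum weights `W_i = N_i / sum(N_i)` (mapped-area shares) and row
#' proportions `p_ij = W_i n_ij / n_i.`, the estimated area proportion of
#' reference class `j` is `p_.j = sum_i p_ij`, its area
#' `A_j = p_.j * A_total`, and its standard error
#' `SE(p_.j) = sqrt(sum_i W_i^2 (n_ij/n_i.)(1 - n_ij/n_i.)/(n_i. - 1))`;
#' the confidence interval is `A_j +/- z * SE * A_total`. Estimated
#' proportions sum to one and areas to the total mapped area, exactly.
#'
#' @param m A `pc_error_matrix`.
#' @param z Critical value for the interval (default 1.96 for 95%
#'   confidence).
#' @return A tibble of class `pc_area_estimate`: `class_id`,
#'   `class_name`, `w` (stratum weight), `p_hat`, `area_ha`, `se_ha`,
#'   `ci_lo_ha`, `ci_hi_ha`; attributes `a_total_ha`, `z`, `pixel_area`.
#' @export
error_adjusted_areas <- function(m, z = 1.96) {
  cm <- m$counts
  k <- nrow(cm)
  N <- m$mapped_pixels
  if (sum(N) <= 0) stopf("no mapped pixels")
  W <- N / sum(N)
  ns <- rowSums(cm)
  bad <- which(W > 0 & ns <= 1)
  if (length(bad))
    stopf("stratum '%s' has <= 1 test sample; variance undefined",
          paste(m$classes[bad], collapse = "', '"))
  A_total <- sum(N) * m$pixel_area
  prop <- matrix(0, k, k)
  use <- which(ns > 0)
  prop[use, ] <- cm[use, , drop = FALSE] / ns[use]
  p_hat <- colSums(W * prop)
  varp <- sapply(seq_len(k), function(j) {
    i <- use
    sum(W[i]^2 * prop[i, j] * (1 - prop[i, j]) / (ns[i] - 1))
  })
  se <- sqrt(varp)
  out <- tibble(
    class_id = seq_len(k), class_name = m$classes,
    w = as.numeric(W), p_hat = as.numeric(p_hat),
    area_ha = p_hat * A_total, se_ha = se * A_total,
    ci_lo_ha = (p_hat - z * se) * A_total,
    ci_hi_ha = (p_hat + z * se) * A_total
  )
  attr(out, "a_total_ha") <- A_total
  attr(out, "z") <- z
  attr(out, "pixel_area") <- m$pixel_area
  class(out) <- c("pc_area_estimate", class(out))
  out
}

#' Monte-Carlo coverage of the area-estimator confidence intervals
#'
#' Simulates repeated stratified reference sampling from a known
#' landscape and confusion model, re-estimates the class areas each
#' time, and reports the fraction of replicates whose confidence
#' interval contains the true area — an empirical check that a nominal
#' 95% interval covers about 95% of the time.
#'
#' The confusion model is the matrix `P(map = i | true = j)` (columns sum
#' to one). Mapped stratum weights follow from the true proportions;
#' `n_test` is allocated to strata proportionally and reference labels
#' are drawn from each stratum's conditional reference distribution.
#'
#' @param true_prop True class proportions (sum to 1).
#' @param confusion K x K column-stochastic confusion model.
#' @param n_test Total test samples per replicate (default 500).
#' @param reps Number of replicates (>= 100; default 1000).
#' @param z Interval critical value (default 1.96).
#' @param a_total_ha Total area (scale only; default 1000).
#' @param seed Integer RNG seed.
#' @return A tibble: `class_id`, `class_name` (when K = 6), `true_area_ha`,
#'   `coverage`, `mean_ci_halfwidth_ha`. A zero-variance (identity)
#'   confusion model is flagged with a message: coverage is trivially 1.
#' @export
coverage_simulation <- function(true_prop, confusion, n_test = 500,
                                reps = 1000, z = 1.96, a_total_ha = 1000,
                                seed = 1) {
  if (reps < 100) stopf("`reps` must be >= 100")
  k <- length(true_prop)
  if (abs(sum(true_prop) - 1) > 1e-8) stopf("`true_prop` must sum to 1")
  confusion <- as.matrix(confusion)
  if (any(abs(colSums(confusion) - 1) > 1e-8))
    stopf("`confusion` columns must each sum to 1")
  degenerate <- all(abs(confusion - diag(k)) < 1e-12)
  if (degenerate)
    inform("zero-variance confusion model: coverage is trivially 1")
  W <- as.numeric(confusion %*% true_prop)            # mapped shares
  q <- sweep(confusion * rep(true_prop, each = k), 1, pmax(W, 1e-300), "/")
  q[W == 0, ] <- 1 / k                                # unused strata (weight 0)
  n_i <- round(W * n_test)
  n_i[n_i < 2] <- 2
  N_pix <- round(W * 1e6)
  set.seed(seed)
  cover <- matrix(FALSE, reps, k)
  halfw <- matrix(NA_real_, reps, k)
  for (r in seq_len(reps)) {
    cm <- matrix(0L, k, k)
    for (i in seq_len(k)) cm[i, ] <- as.integer(rmultinom(1, n_i[i], q[i, ]))
    em <- error_matrix_from_counts(cm, N_pix, pixel_area = a_total_ha / sum(N_pix),
                                   class_names = paste0("class_", seq_len(k)))
    est <- error_adjusted_areas(em, z = z)
    truth_area <- true_prop * a_total_ha
    cover[r, ] <- est$ci_lo_ha <= truth_area & truth_area <= est$ci_hi_ha
    halfw[r, ] <- (est$ci_hi_ha - est$ci_lo_ha) / 2
  }
  out <- tibble(class_id = seq_len(k),
                true_area_ha = true_prop * a_total_ha,
                coverage = colMeans(cover),
                mean_ci_halfwidth_ha = colMeans(halfw))
  if (k == 6) out$class_name <- lc_classes()$class_name
  out
}

#' Write / read an error matrix as labelled CSV
#'
#' @param m A `pc_error_matrix`.
#' @param path Output CSV path.
#' @return `path` invisibly; the reader returns the `pc_error_matrix`.
#' @export
write_error_matrix_csv <- function(m, path) {
  df <- as.data.frame(m$counts)
  df <- cbind(map_class = rownames(m$counts), df,
              mapped_pixels = m$mapped_pixels,
              pixel_area_ha = m$pixel_area)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_error_matrix_csv
#' @export
read_error_matrix_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  cls <- df$map_class
  counts <- as.matrix(df[, cls, drop = FALSE])
  rownames(counts) <- cls
  error_matrix_from_counts(counts, df$mapped_pixels, df$pixel_area_ha[1],
                           class_names = cls)
}
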