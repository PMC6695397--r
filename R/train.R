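#' Extract labelled reference pixels from polygons
#'
#' One sample per analysis-grid pixel whose centre falls inside a
#' reference polygon; each sample carries its grid indices, class label,
#' polygon provenance and the 17 feature values. Polygons covering no
#' pixel centre (e.g. lying outside the raster) contribute zero samples
#' with a warning; samples with any missing feature are dropped with a
#' message.
#'
#' @param polygons Reference-polygon tibble (`polygon_id`, `class_id`,
#'   `geometry`).
#' @param stack A 17-band `pc_raster` feature stack.
#' @return A tibble: `polygon_id`, `class_id`, `row`, `col`, then one
#'   column per feature.
#' @export
extract_reference_pixels <- function(polygons, stack) {
  if (!all(c("polygon_id", "class_id", "geometry") %in% names(polygons)))
    stopf("`polygons` needs columns polygon_id, class_id, geometry")
  d <- dim(stack$values)[1:2]
  nms <- dimnames(stack$values)[[3]]
  rows <- vector("list", nrow(polygons))
  for (i in seq_len(nrow(polygons))) {
    mask <- polygon_pixel_mask(stack, polygons$geometry[[i]])
    idx <- which(mask)
    if (!length(idx)) {
      warn(sprintf("polygon %s covers no pixel centre; 0 samples",
                   polygons$polygon_id[i]))
      next
    }
    r <- (idx - 1L) %% d[1] + 1L
    cc <- (idx - 1L) %/% d[1] + 1L
    feats <- sapply(nms, function(b) stack$values[, , b][idx])
    if (length(idx) == 1L) feats <- matrix(feats, nrow = 1,
                                           dimnames = list(NULL, nms))
    tb <- tibble(polygon_id = polygons$polygon_id[i],
                 class_id = polygons$class_id[i], row = r, col = cc)
    rows[[i]] <- dplyr::bind_cols(tb, as_tibble(feats))
  }
  out <- bind_rows(rows)
  if (nrow(out)) {
    ok <- stats::complete.cases(out[nms])
    if (any(!ok)) {
      inform(sprintf("dropped %d sample(s) with missing features", sum(!ok)))
      out <- out[ok, ]
    }
  }
  out
}

#' Stratified train/test split of reference samples
#'
#' Within each class, a seeded shuffle sends `floor(fraction * n)`
#' samples to training and the remainder to testing; the two roles are
#' disjoint and exhaustive.
#'
#' @param samples Sample tibble from [extract_reference_pixels()].
#' @param fraction Training fraction in `(0, 1)` (default 0.5).
#' @param seed Integer RNG seed for the shuffle.
#' @return The input tibble with an added `role` column
#'   (`"train"`/`"test"`).
#' @export
split_reference <- function(samples, fraction = 0.5, seed = 1) {
  if (!(fraction > 0 && fraction < 1)) stopf("`fraction` must be in (0, 1)")
  cn <- lc_classes()
  counts <- table(samples$class_id)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    nm <- cn$class_name[match(as.integer(small), cn$class_id)]
    stopf("class '%s' has fewer than 2 samples; cannot split",
          paste(nm, collapse = "', '"))
  }
  set.seed(seed)
  samples$role <- NA_character_
  for (cc in sort(unique(samples$class_id))) {
    idx <- which(samples$class_id == cc)
    n_tr <- floor(fraction * length(idx))
    tr <- sample(idx, n_tr)
    samples$role[tr] <- "train"
    samples$role[setdiff(idx, tr)] <- "test"
  }
  samples
}

#' Train the random-forest land-cover classifier
#'
#' Fits a random forest over the 17 features with the pipeline's
#' defaults: 100 trees and 4 candidate predictors per node
#' (`round(sqrt(17))`). The fit is seeded so retraining reproduces
#' predictions exactly.
#'
#' @param train_samples Sample tibble with `class_id` and the feature
#'   columns, usually `role == "train"` rows from [split_reference()].
#' @param n_trees Number of trees (default 100).
#' @param m_try Candidate predictors per split (default `round(sqrt(17))`
#'   = 4).
#' @param seed Integer RNG seed.
#' @param features Feature column names (default [feature_names()],
#'   restricted to the columns present).
#' @return A `pc_classifier` wrapping the fitted forest, feature order
#'   and class levels.
#' @export
train_classifier <- function(train_samples, n_trees = 100,
                             m_try = round(sqrt(17)), seed = 1,
                             features = NULL) {
  features <- features %||% intersect(feature_names(), names(train_samples))
  if (!length(features)) stopf("no feature columns found in `train_samples`")
  if (n_trees < 1) stopf("`n_trees` must be >= 1")
  lv <- sort(unique(train_samples$class_id))
  if (length(lv) < 2)
    stopf("training data holds a single class; need at least two")
  if (m_try < 1 || m_try > length(features))
    stopf("`m_try` must be between 1 and the number of features")
  x <- as.data.frame(train_samples[features])
  y <- factor(train_samples$class_id, levels = lv)
  set.seed(seed)
  rf <- randomForest::randomForest(x = x, y = y, ntree = n_trees,
                                   mtry = m_try)
  structure(list(rf = rf, features = features, classes = lv,
                 n_trees = n_trees, m_try = m_try, seed = seed),
            class = "pc_classifier")
}

#' @export
print.pc_classifier <- function(x, ...) {
  cat(sprintf("<pc_classifier> random forest: %d trees, mtry %d, %d classes, %d features\n",
              x$n_trees, x$m_try, length(x$classes), length(x$features)))
  invisible(x)
}

#' @export
tidy.pc_classifier <- function(x, ...) {
  imp <- randomForest::importance(x$rf)
  tibble(feature = rownames(imp), importance = as.numeric(imp[, 1]))
}

#' @export
glance.pc_classifier <- function(x, ...) {
  tibble(n_trees = x$n_trees, m_try = x$m_try,
         n_classes = length(x$classes),
         oob_error = as.numeric(x$rf$err.rate[x$n_trees, "OOB"]))
}

#' Predict the class map from a feature stack
#'
#' @param model A `pc_classifier`.
#' @param stack A `pc_raster` feature stack whose bands include the
#'   model's features in the training order.
#' @return A `pc_raster` of integer class codes; pixels with any missing
#'   feature are missing.
#' @export
predict_map <- function(model, stack) {
  nms <- dimnames(stack$values)[[3]]
  miss <- setdiff(model$features, nms)
  if (length(miss))
    stopf("stack lacks feature layer(s) %s; expected order: %s",
          paste(miss, collapse = ", "), paste(model$features, collapse = ", "))
  d <- dim(stack$values)[1:2]
  flat <- sapply(model$features, function(b) as.vector(stack$values[, , b]))
  ok <- stats::complete.cases(flat)
  out <- rep(NA_integer_, d[1] * d[2])
  if (any(ok)) {
    pred <- stats::predict(model$rf, newdata = as.data.frame(flat[ok, , drop = FALSE]))
    out[ok] <- as.integer(as.character(pred))
  }
  pc_raster(matrix(out, d[1], d[2]), res = stack$res, xmin = stack$xmin,
            ymax = stack$ymax, crs = stack$crs)
}

#' Majority (mode) filter of a class map
#'
#' Replaces each pixel with the modal class of its odd square
#' neighbourhood, counting only valid in-bounds pixels. When the modal
#' count ties with the centre pixel's own class count, the centre class
#' is kept (deterministic, conservative); missing centres stay missing.
#'
#' @param map A `pc_raster` integer class map.
#' @param window Odd window side (default 3).
#' @return A filtered `pc_raster` class map.
#' @export
majority_filter <- function(map, window = 3) {
  window <- as.integer(window)
  if (window < 1 || window %% 2L == 0L)
    stopf("`window` must be an odd positive integer")
  cls <- map$values
  ids <- sort(unique(as.vector(cls[!is.na(cls)])))
  if (!length(ids) || window == 1L) return(map)
  h <- (window - 1L) / 2L
  counts <- lapply(ids, function(cc) {
    ind <- (cls == cc) * 1; ind[is.na(ind)] <- 0
    s <- matrix(0, nrow(cls), ncol(cls))
    for (dr in -h:h) for (dc in -h:h) s <- s + shift_mat(ind, dr, dc, fill = 0)
    s
  })
  best <- matrix(ids[1], nrow(cls), ncol(cls)); best_n <- counts[[1]]
  if (length(ids) > 1) for (j in 2:length(ids)) {
    take <- counts[[j]] > best_n
    best[take] <- ids[j]; best_n[take] <- counts[[j]][take]
  }
  # centre retains its class on ties with the winner
  centre_n <- matrix(0, nrow(cls), ncol(cls))
  for (j in seq_along(ids)) {
    sel <- !is.na(cls) & cls == ids[j]
    centre_n[sel] <- counts[[j]][sel]
  }
  keep <- !is.na(cls) & centre_n == best_n
  out <- best
  out[keep] <- cls[keep]
  out[is.na(cls)] <- NA_integer_
  pc_raster(out, res = map$res, xmin = map$xmin, ymax = map$ymax,
            crs = map$crs)
}
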