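mk_stack <- function(n = 8, res = 20, fill = 0.2) {
  arr <- array(fill, dim = c(n, n, 17),
               dimnames = list(NULL, NULL, feature_names()))
  pc_raster(arr, res = res)
}

poly_tbl <- function(rings, class_id = 1L) {
  tb <- tibble::tibble(polygon_id = seq_along(rings),
                       class_id = rep(class_id, length.out = length(rings)))
  tb$geometry <- rings
  tb
}

test_that("pixel extraction counts centres inside the polygon", {
  st <- mk_stack(8)
  # 2 x 2 block of 20 m pixel centres: centres at 10, 30, 50, ... metres
  ring <- rect_ring(22, 102, 62, 142)
  got <- extract_reference_pixels(poly_tbl(list(ring)), st)
  expect_identical(nrow(got), 4L)
  expect_true(all(feature_names() %in% names(got)))
  off <- rect_ring(1000, 1000, 1100, 1100)
  expect_warning(out <- extract_reference_pixels(poly_tbl(list(off)), st),
                 "no pixel centre")
  expect_identical(nrow(out), 0L)
})

test_that("extraction agrees with a brute-force centre-in-polygon scan", {
  sc <- make_small_scene(seed = 5)
  st <- mk_stack(48, res = 20)
  rp <- sc$reference_polygons[1:25, ]
  got <- extract_reference_pixels(rp, st)
  # independent ray-casting count over the whole grid
  xy <- pixel_centers(st)
  want <- 0L
  for (i in seq_len(nrow(rp))) {
    ring <- rp$geometry[[i]]
    want <- want + sum(vapply(seq_len(nrow(xy)), function(j)
      oracle_point_in_polygon(xy[j, 1], xy[j, 2], ring), logical(1)))
  }
  expect_identical(nrow(got), as.integer(want))
})

test_that("the stratified split follows the floor rule exactly", {
  samples <- tibble::tibble(
    polygon_id = 1, class_id = rep(c(1L, 2L), c(100, 101)),
    row = 1, col = 1
  )
  sp <- split_reference(samples, fraction = 0.5, seed = 3)
  tab <- table(sp$class_id, sp$role)
  expect_identical(as.integer(tab["1", c("test", "train")]), c(50L, 50L))
  expect_identical(as.integer(tab["2", c("test", "train")]), c(51L, 50L))
  expect_true(all(sp$role %in% c("train", "test")))
  tiny <- tibble::tibble(polygon_id = 1, class_id = c(1L, 1L, 2L),
                         row = 1, col = 1)
  expect_error(split_reference(tiny), "fewer than 2")
  expect_error(split_reference(samples, fraction = 1), "fraction")
})

test_that("splits are seeded, disjoint and exhaustive per class", {
  n <- 200
  samples <- tibble::tibble(polygon_id = rep(1:20, each = 10),
                            class_id = rep(1:5, each = 40),
                            row = seq_len(n), col = 1)
  a <- split_reference(samples, seed = 9)
  b <- split_reference(samples, seed = 9)
  expect_identical(a$role, b$role)
  for (cc in 1:5) {
    idx <- samples$class_id == cc
    expect_identical(sum(a$role[idx] == "train"), 20L)
    expect_identical(sum(a$role[idx] == "test"), 20L)
  }
})

test_that("the forest separates a separable toy problem and is seeded", {
  set.seed(1)
  n <- 60
  toy <- tibble::tibble(class_id = rep(c(1L, 2L), each = n),
                        B2 = c(runif(n, -1, 0), runif(n, 1, 2)))
  mod <- train_classifier(toy, n_trees = 50, m_try = 1, seed = 7,
                          features = "B2")
  pred <- stats::predict(mod$rf, newdata = data.frame(B2 = toy$B2))
  expect_equal(mean(pred == toy$class_id), 1.0)
  grid <- data.frame(B2 = seq(-1, 2, length.out = 200))
  mod2 <- train_classifier(toy, n_trees = 50, m_try = 1, seed = 7,
                           features = "B2")
  expect_identical(stats::predict(mod$rf, grid), stats::predict(mod2$rf, grid))
  expect_error(train_classifier(toy[toy$class_id == 1, ], features = "B2"),
               "single class")
})

test_that("the default predictors-per-split equals round(sqrt(17)) = 4", {
  expect_identical(formals(train_classifier)$m_try, quote(round(sqrt(17))))
  expect_identical(eval(formals(train_classifier)$m_try), 4)
  expect_identical(formals(pipeline_config)$m_try, 4)
})

test_that("prediction inverts the noiseless generative model", {
  tm <- generate_class_map(48, 48, rep(1 / 6, 6), patch_scale = 6, seed = 8,
                           block = 2)
  sig <- lc_signatures()
  sig$optical_sd <- lapply(sig$optical_sd, function(s) s * 0)
  sig$sar_sd <- lapply(sig$sar_sd, function(s) s * 0)
  opt <- generate_optical_series(tm, sig, n_dates = 3, cloud_fraction = 0,
                                 seed = 1, persistent_brightness = 0,
                                 persistent_vigour = 0, confusion_amp = 0)
  sar <- generate_sar_series(tm, sig, n_dates = 3, seed = 1,
                             persistent_sd = 0, confusion_amp = 0)
  comp <- percentile_mean_composite(opt, min_obs = 1)
  nd <- ndvi(comp)
  dem <- pc_raster(matrix(100, 16, 16), res = 30)
  st <- build_feature_stack(comp, nd, moving_sd(nd, 5),
                            sar_temporal_stats(sar), slope(dem))
  anc <- generate_ancillary(tm, n_reference_polygons_per_class = 8, seed = 2,
                            ref_poly_size = 20)
  samp <- extract_reference_pixels(anc$reference_polygons, st)
  samp <- split_reference(samp, seed = 1)
  mod <- train_classifier(samp[samp$role == "train", ], seed = 3)
  map <- predict_map(mod, st)
  truth20 <- aggregate_modal(tm, 2)
  expect_identical(map$values, truth20$values)
})

test_that("prediction propagates missing features and checks layers", {
  st <- mk_stack(6)
  toy <- tibble::tibble(class_id = rep(c(1L, 2L), each = 20),
                        B2 = rep(c(0, 1), each = 20))
  mod <- train_classifier(toy, n_trees = 20, m_try = 1, seed = 1,
                          features = "B2")
  st$values[2, 3, "B2"] <- NA
  map <- predict_map(mod, st)
  expect_true(is.na(map$values[2, 3]))
  expect_identical(sum(is.na(map$values)), 1L)
  bad <- mk_stack(6)
  dimnames(bad$values)[[3]][1] <- "NOT_A_BAND"
  expect_error(predict_map(mod, bad), "expected order")
})

test_that("the majority filter votes, keeps ties and preserves values", {
  u <- pc_raster(matrix(4L, 7, 7), res = 20)
  expect_identical(majority_filter(u)$values, u$values)
  m <- matrix(1L, 5, 5); m[3, 3] <- 2L
  got <- majority_filter(pc_raster(m, res = 20))
  expect_identical(got$values[3, 3], 1L)
  # 4 votes class 1 vs 4 votes class 2 (centre included): a tied centre
  # keeps its own class
  tie <- matrix(c(1L, 1L, 3L,
                  1L, 2L, 2L,
                  1L, 2L, 2L), 3, 3, byrow = TRUE)
  expect_identical(majority_filter(pc_raster(tie, res = 20))$values[2, 2], 2L)
  # missing centres stay missing; missing neighbours cast no vote
  mna <- m; mna[1, 1] <- NA
  gna <- majority_filter(pc_raster(mna, res = 20))
  expect_true(is.na(gna$values[1, 1]))
  # value-range preservation on random maps
  set.seed(5)
  for (i in 1:10) {
    r <- pc_raster(matrix(sample(c(2L, 5L, 6L), 64, TRUE), 8, 8), res = 20)
    f <- majority_filter(r)
    expect_true(all(f$values %in% c(2L, 5L, 6L)))
  }
})

test_that("filtering denoises salt-and-pepper corruption", {
  tm <- generate_class_map(96, 96, rep(1 / 6, 6), patch_scale = 12, seed = 6)
  set.seed(10)
  noisy <- tm$values
  flip <- sample(length(noisy), round(0.06 * length(noisy)))
  noisy[flip] <- sample(1:6, length(flip), TRUE)
  noisy_r <- pc_raster(noisy, res = 10)
  once <- majority_filter(noisy_r)
  acc_pre <- mean(noisy == tm$values)
  acc_post <- mean(once$values == tm$values)
  expect_gt(acc_post, acc_pre)
  # repeated filtering converges: a second pass changes fewer pixels
  twice <- majority_filter(once)
  expect_lte(sum(twice$values != once$values), sum(once$values != noisy))
})
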