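test_that("degenerate class weights yield a single-class map", {
  tm <- generate_class_map(40, 30, c(1, 0, 0, 0, 0, 0), patch_scale = 4, seed = 9)
  expect_true(all(tm$values == 1L))
  tm2 <- generate_class_map(40, 30, c(0, 0, 0, 0, 0, 1), patch_scale = 4, seed = 9)
  expect_true(all(tm2$values == 6L))
})

test_that("class frequencies track the requested weights", {
  tm <- generate_class_map(512, 512, rep(1 / 6, 6), patch_scale = 8, seed = 7)
  freq <- tabulate(tm$values, 6) / length(tm$values)
  expect_true(all(abs(freq - 1 / 6) < 0.10))
  w <- c(0.12, 0.15, 0.40, 0.18, 0.09, 0.06)
  tm2 <- generate_class_map(256, 256, w, patch_scale = 16, seed = 2)
  expect_true(all(abs(tabulate(tm2$values, 6) / 256^2 - w) < 0.05))
})

test_that("the generator is deterministic and validates arguments", {
  a <- generate_class_map(64, 64, rep(1 / 6, 6), patch_scale = 6, seed = 5)
  b <- generate_class_map(64, 64, rep(1 / 6, 6), patch_scale = 6, seed = 5)
  expect_identical(a$values, b$values)
  expect_error(generate_class_map(0, 10, rep(1 / 6, 6)), "size")
  expect_error(generate_class_map(10, 10, c(-1, 2, 0, 0, 0, 0)), "non-negative")
  expect_error(generate_class_map(10, 10, rep(0, 6)), "non-negative")
})

test_that("block alignment snaps patch boundaries to analysis cells", {
  tm <- generate_class_map(128, 128, rep(1 / 6, 6), patch_scale = 12,
                           seed = 4, block = 2)
  v <- tm$values
  blocks <- v[seq(1, 127, 2), seq(1, 127, 2)]
  expect_identical(v[seq(2, 128, 2), seq(1, 127, 2)], blocks)
  expect_identical(v[seq(1, 127, 2), seq(2, 128, 2)], blocks)
})

test_that("noiseless optical series reproduces the signature image", {
  tm <- generate_class_map(32, 32, rep(1 / 6, 6), patch_scale = 4, seed = 1)
  sig <- lc_signatures()
  sig$optical_sd <- lapply(sig$optical_sd, function(s) s * 0)
  st <- generate_optical_series(tm, sig, n_dates = 3, cloud_fraction = 0,
                                seed = 2, persistent_brightness = 0,
                                persistent_vigour = 0, confusion_amp = 0)
  mu <- do.call(rbind, sig$optical_mean)
  for (d in 1:3) {
    expect_false(any(st$qa[[d]]))
    for (b in seq_along(optical_bands())) {
      expect_equal(st$bands[[d]][, , b],
                   matrix(mu[tm$values, b], 32, 32), tolerance = 1e-12)
    }
  }
})

test_that("cloud masks hit the requested per-date fraction", {
  tm <- generate_class_map(96, 96, rep(1 / 6, 6), patch_scale = 8, seed = 1)
  st <- generate_optical_series(tm, n_dates = 12, cloud_fraction = 0.3, seed = 11)
  shares <- vapply(st$qa, mean, numeric(1))
  expect_true(all(abs(shares - 0.3) < 0.05))
  st_all <- generate_optical_series(tm, n_dates = 2, cloud_fraction = 1, seed = 1)
  expect_true(all(vapply(st_all$qa, all, logical(1))))
  expect_error(generate_optical_series(tm, n_dates = 2, cloud_fraction = 1.2),
               "cloud_fraction")
})

test_that("optical generation requires a signature for every class", {
  tm <- generate_class_map(16, 16, rep(1 / 6, 6), patch_scale = 2, seed = 3)
  sig <- lc_signatures()[1:4, ]
  expect_error(generate_optical_series(tm, sig, n_dates = 1), "signature")
})

test_that("radar speckle is unbiased in dB and disabled by zero sd", {
  tm <- generate_class_map(64, 64, rep(1 / 6, 6), patch_scale = 6, seed = 2)
  sig <- lc_signatures()
  st <- generate_sar_series(tm, sig, n_dates = 12, seed = 3,
                            persistent_sd = 0, confusion_amp = 0)
  stats4 <- sar_temporal_stats(st)
  mu_vv <- vapply(sig$sar_mean, `[[`, numeric(1), "VV")
  for (cc in 1:6) {
    got <- mean(band(stats4, "VV_mean")[tm$values == cc])
    expect_lt(abs(got - mu_vv[cc]), 0.3)
  }
  sig0 <- sig
  sig0$sar_sd <- lapply(sig0$sar_sd, function(s) s * 0)
  st0 <- generate_sar_series(tm, sig0, n_dates = 2, seed = 4,
                             persistent_sd = 0, confusion_amp = 0)
  expect_equal(st0$vv[[1]], matrix(mu_vv[tm$values], 64, 64), tolerance = 1e-12)
  expect_identical(st0$vv[[1]], st0$vv[[2]])
})

test_that("single-date radar stacks have zero temporal SD downstream", {
  tm <- generate_class_map(24, 24, rep(1 / 6, 6), patch_scale = 3, seed = 5)
  st <- generate_sar_series(tm, n_dates = 1, seed = 1)
  s4 <- sar_temporal_stats(st)
  expect_true(all(band(s4, "VV_sd") == 0))
  expect_true(all(band(s4, "VH_sd") == 0))
})

test_that("ancillary layers honour counts, purity and the flat-DEM option", {
  sc <- make_small_scene(seed = 3, dem = "flat")
  expect_true(all(slope(sc$dem)$values == 0))
  # every reference polygon covers native truth pixels of exactly one class
  for (i in seq_len(nrow(sc$reference_polygons))) {
    mask <- palmcover:::polygon_pixel_mask(sc$truth,
                                           sc$reference_polygons$geometry[[i]])
    cls <- unique(sc$truth$values[mask])
    expect_length(cls, 1)
    expect_identical(cls, sc$reference_polygons$class_id[i])
  }
  counts <- table(sc$reference_polygons$class_id)
  expect_identical(length(counts), 6L)
  kinds <- table(sc$zones$kind)
  expect_identical(as.integer(kinds[c("concession", "district", "park")]),
                   c(4L, 2L, 1L))
})

test_that("a fixed per-class polygon request returns that many polygons", {
  tm <- generate_class_map(128, 128, rep(1 / 6, 6), patch_scale = 12,
                           seed = 4, block = 2)
  anc <- generate_ancillary(tm, n_reference_polygons_per_class = 5, seed = 1,
                            ref_poly_size = 20)
  expect_identical(nrow(anc$reference_polygons), 30L)
})

test_that("impossible polygon placement fails naming the class", {
  tm <- generate_class_map(40, 40, c(0.999, 0.001, 0, 0, 0, 0),
                           patch_scale = 2, seed = 1)
  expect_error(
    generate_ancillary(tm, n_reference_polygons_per_class = 5, seed = 1,
                       ref_poly_size = 400),
    class = "palmcover_placement_error"
  )
})

test_that("scene simulation is deterministic under a fixed master seed", {
  a <- make_small_scene(seed = 7)
  b <- make_small_scene(seed = 7)
  expect_identical(a$truth$values, b$truth$values)
  expect_identical(a$optical$bands[[1]], b$optical$bands[[1]])
  expect_identical(a$sar$vv[[2]], b$sar$vv[[2]])
  expect_identical(a$zones$geometry, b$zones$geometry)
})

test_that("modal aggregation picks the block majority", {
  m <- pc_raster(matrix(c(1L, 1L, 2L, 1L,   # column-major 2x2 blocks
                          3L, 3L, 3L, 3L), 2, 4), res = 10)
  got <- aggregate_modal(m, 2)
  expect_identical(as.vector(got$values), c(1L, 3L))
  expect_equal(got$res, 20)
})
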