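test_that("a perfect map yields a diagonal error matrix", {
  map <- pc_raster(matrix(rep(1:6, each = 4), 4, 6), res = 20)
  test <- tibble::tibble(row = rep(1:4, 6), col = rep(1:6, each = 4),
                         class_id = rep(1:6, each = 4))
  em <- error_matrix(test, map, pixel_area = 0.04)
  expect_true(all(em$counts[upper.tri(em$counts)] == 0))
  expect_true(all(em$counts[lower.tri(em$counts)] == 0))
  expect_identical(sum(em$counts), 24L)
  expect_identical(em$mapped_pixels, rep(4, 6))
})

test_that("test pixels on missing map cells are excluded, not counted", {
  v <- matrix(rep(1:6, each = 4), 4, 6); v[1, 1] <- NA
  map <- pc_raster(v, res = 20)
  test <- tibble::tibble(row = rep(1:4, 6), col = rep(1:6, each = 4),
                         class_id = rep(1:6, each = 4))
  expect_message(em <- error_matrix(test, map, 0.04), "excluded 1")
  expect_identical(sum(em$counts), 23L)
  expect_identical(em$n_excluded, 1L)
})

test_that("planted label corruption is recovered in the off-diagonals", {
  tm <- generate_class_map(64, 64, rep(1 / 6, 6), patch_scale = 6, seed = 12)
  set.seed(3)
  n <- 1200
  idx <- sample(length(tm$values), n)
  ref <- tm$values[idx]
  corrupt <- runif(n) < 0.10
  ref[corrupt] <- 1L + (ref[corrupt] + sample(0:4, sum(corrupt), TRUE)) %% 6L
  test <- tibble::tibble(row = (idx - 1L) %% 64L + 1L,
                         col = (idx - 1L) %/% 64L + 1L,
                         class_id = as.integer(ref))
  em <- error_matrix(test, tm, 0.04)
  off <- 1 - sum(diag(em$counts)) / sum(em$counts)
  expect_lt(abs(off - 0.10), 0.03)
})

test_that("accuracy metrics match hand arithmetic", {
  em <- error_matrix_from_counts(matrix(c(45, 10, 5, 40), 2, 2),
                                 mapped_pixels = c(600, 400),
                                 pixel_area = 1)
  a <- accuracy_metrics(em)
  expect_equal(a$overall, 0.85)
  expect_equal(a$per_class$ua[1], 0.90)
  expect_equal(a$per_class$pa[1], 45 / 55, tolerance = 1e-12)
  expect_equal(a$overall_area_weighted, 0.6 * 0.9 + 0.4 * 0.8)
  idm <- error_matrix_from_counts(diag(6) * 10, rep(100, 6), 0.04)
  ai <- accuracy_metrics(idm)
  expect_equal(ai$overall, 1)
  expect_true(all(ai$per_class$ua == 1) && all(ai$per_class$pa == 1))
  uni <- error_matrix_from_counts(matrix(5, 4, 4), rep(10, 4), 1,
                                  class_names = paste0("c", 1:4))
  expect_equal(accuracy_metrics(uni)$overall, 1 / 4)
})

test_that("undefined per-class accuracies are missing, never zero", {
  cm <- matrix(0, 3, 3); cm[1, 1] <- 10; cm[2, 1] <- 2; cm[2, 2] <- 8
  em <- error_matrix_from_counts(cm, c(50, 50, 0), 1,
                                 class_names = paste0("c", 1:3))
  a <- accuracy_metrics(em)
  expect_true(is.na(a$per_class$ua[3]))
  expect_true(is.na(a$per_class$pa[3]))
})

test_that("error-adjusted areas reproduce the frozen two-stratum oracle", {
  counts <- matrix(c(45, 10, 5, 40), 2, 2)
  N <- c(0.6, 0.4) * 25000                 # 1000 ha at 0.04 ha/pixel
  em <- error_matrix_from_counts(counts, N, pixel_area = 0.04,
                                 class_names = c("a", "b"))
  est <- error_adjusted_areas(em, z = 1.96)
  # frozen from the independent arithmetic oracle (hand/spreadsheet):
  # p.1 = 0.6*45/50 + 0.4*10/50 = 0.62 -> 620 ha; SE = sqrt((0.36*0.09 +
  # 0.16*0.16)/49) = 0.03440455 -> 34.40455 ha; z*SE = 67.43292 ha
  expect_equal(est$area_ha, c(620, 380), tolerance = 0.01 / 620)
  expect_equal(est$se_ha, c(34.40455, 34.40455), tolerance = 1e-5)
  expect_equal(est$ci_lo_ha, c(552.56708, 312.56708), tolerance = 1e-4)
  expect_equal(est$ci_hi_ha, c(687.43292, 447.43292), tolerance = 1e-4)
  orc <- oracle_adjusted_areas(counts, N, 0.04)
  expect_equal(est$area_ha, orc$area, tolerance = 1e-12)
  expect_equal(est$se_ha, orc$se, tolerance = 1e-12)
})

test_that("estimated areas always sum to the total mapped area", {
  set.seed(21)
  for (case in 1:1000) {
    k <- sample(2:6, 1)
    counts <- matrix(rpois(k * k, 4) + diag(k) * rpois(k, 30), k, k)
    bad_rows <- rowSums(counts) <= 1
    counts[bad_rows, ] <- counts[bad_rows, ] + 2L
    N <- sample(100:10000, k)
    em <- error_matrix_from_counts(counts, N, pixel_area = 0.04,
                                   class_names = paste0("c", seq_len(k)))
    est <- error_adjusted_areas(em)
    expect_equal(sum(est$area_ha), sum(N) * 0.04, tolerance = 1e-8)
    expect_equal(sum(est$p_hat), 1, tolerance = 1e-12)
    expect_true(all(est$ci_lo_ha <= est$area_ha + 1e-9))
    expect_true(all(est$ci_hi_ha >= est$area_ha - 1e-9))
  }
})

test_that("perfect classification recovers mapped areas with zero SE", {
  em <- error_matrix_from_counts(diag(6) * 20,
                                 mapped_pixels = c(100, 200, 300, 150, 150, 100),
                                 pixel_area = 0.04)
  est <- error_adjusted_areas(em)
  expect_equal(est$area_ha, c(100, 200, 300, 150, 150, 100) * 0.04)
  expect_true(all(est$se_ha == 0))
})

test_that("the estimator is invariant to uniform within-stratum scaling", {
  counts <- matrix(c(45, 10, 5, 40), 2, 2)
  N <- c(600, 400)
  a <- error_adjusted_areas(error_matrix_from_counts(counts, N, 1,
                                                     class_names = c("a", "b")))
  counts2 <- counts; counts2[1, ] <- counts2[1, ] * 3
  b <- error_adjusted_areas(error_matrix_from_counts(counts2, N, 1,
                                                     class_names = c("a", "b")))
  expect_equal(a$area_ha, b$area_ha, tolerance = 1e-12)
})

test_that("thin strata are a hard error naming the stratum", {
  cm <- matrix(c(1, 0, 0, 40), 2, 2)
  em <- error_matrix_from_counts(cm, c(10, 10), 1, class_names = c("aa", "bb"))
  expect_error(error_adjusted_areas(em), "aa")
})

test_that("a zero-confusion model gives trivial full coverage", {
  expect_message(
    cov <- coverage_simulation(rep(1 / 6, 6), diag(6), n_test = 120,
                               reps = 100, seed = 2),
    "trivially"
  )
  expect_true(all(cov$coverage == 1))
  expect_true(all(cov$mean_ci_halfwidth_ha == 0))
})

test_that("interval width shrinks like one over root n", {
  conf <- matrix(0.04 / 5, 6, 6); diag(conf) <- 0.96
  w1 <- coverage_simulation(rep(1 / 6, 6), conf, n_test = 400, reps = 150,
                            seed = 5)$mean_ci_halfwidth_ha
  w2 <- coverage_simulation(rep(1 / 6, 6), conf, n_test = 800, reps = 150,
                            seed = 6)$mean_ci_halfwidth_ha
  expect_true(all(abs(w1 / w2 - sqrt(2)) < 0.2 * sqrt(2)))
})

test_that("error matrices round-trip through labelled CSV", {
  em <- error_matrix_from_counts(matrix(c(45, 10, 5, 40), 2, 2),
                                 c(600, 400), 0.04,
                                 class_names = c("a", "b"))
  path <- tempfile(fileext = ".csv")
  write_error_matrix_csv(em, path)
  back <- read_error_matrix_csv(path)
  expect_equal(back$counts, em$counts)
  expect_equal(back$mapped_pixels, em$mapped_pixels)
  expect_equal(back$pixel_area, em$pixel_area)
})

test_that("tidy and glance expose the broom-style summaries", {
  em <- error_matrix_from_counts(matrix(c(45, 10, 5, 40), 2, 2),
                                 c(600, 400), 0.04,
                                 class_names = c("a", "b"))
  td <- tidy(em)
  expect_identical(names(td), c("class_id", "class_name", "n_map", "n_ref",
                                "ua", "pa"))
  gl <- glance(em)
  expect_equal(gl$overall, 0.85)
  expect_equal(gl$n_test, 100)
})
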