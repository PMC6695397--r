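#' Pipeline configuration
#'
#' Builds and validates the full configuration of one reproducible run:
#' scene-generation conditions, compositing parameters, classifier
#' specification, split fraction, seeds, interval multiplier and
#' reporting conventions. The object round-trips losslessly through
#' YAML via [write_config()] / [read_config()].
#'
#' @param out_dir Run directory for artifacts (created by
#'   [run_pipeline()]).
#' @param size,n_optical,n_sar,cloud_fraction,patch_scale,class_weights
#'   Scene conditions (see [simulate_scene()]).
#' @param n_concessions,n_reference_polygons_per_class Vector layers.
#' @param p_lo,p_hi,min_obs Compositing window and minimum clear
#'   observations.
#' @param blue_threshold,swir_threshold,cirrus_threshold Cloud rule.
#' @param n_trees,m_try Random-forest specification.
#' @param split_fraction Training fraction.
#' @param out_res Analysis cell size, metres.
#' @param z Confidence-interval multiplier.
#' @param seed Master seed; `split_seed` and `model_seed` are separate
#'   keys (both logged) defaulting to offsets of it.
#' @param split_seed,model_seed Seeds for the split shuffle and the
#'   forest.
#' @return A validated list of class `pc_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("palmcover_run_"),
                            size = 256, n_optical = 8, n_sar = 12,
                            cloud_fraction = 0.3, patch_scale = 32,
                            class_weights = c(0.12, 0.15, 0.40, 0.18, 0.09, 0.06),
                            n_concessions = 4,
                            n_reference_plots = 1200,
                            p_lo = 40, p_hi = 60, min_obs = 3,
                            blue_threshold = 0.25, swir_threshold = 0.20,
                            cirrus_threshold = 0.01,
                            n_trees = 100, m_try = 4,
                            split_fraction = 0.5, out_res = 20, z = 1.96,
                            seed = 1, split_seed = NULL, model_seed = NULL) {
  cfg <- list(out_dir = out_dir, size = size, n_optical = n_optical,
              n_sar = n_sar, cloud_fraction = cloud_fraction,
              patch_scale = patch_scale, class_weights = class_weights,
              n_concessions = n_concessions,
              n_reference_plots = n_reference_plots,
              p_lo = p_lo, p_hi = p_hi, min_obs = min_obs,
              blue_threshold = blue_threshold, swir_threshold = swir_threshold,
              cirrus_threshold = cirrus_threshold,
              n_trees = n_trees, m_try = m_try,
              split_fraction = split_fraction, out_res = out_res, z = z,
              seed = seed,
              split_seed = split_seed %||% (seed + 101L),
              model_seed = model_seed %||% (seed + 211L))
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (!(cfg$p_lo >= 0 && cfg$p_lo < cfg$p_hi && cfg$p_hi <= 100))
    stopf("invalid composite window: need 0 <= p_lo < p_hi <= 100")
  if (cfg$cloud_fraction < 0 || cfg$cloud_fraction > 1)
    stopf("cloud_fraction must be in [0, 1]")
  if (!(cfg$split_fraction > 0 && cfg$split_fraction < 1))
    stopf("split_fraction must be in (0, 1)")
  if (length(cfg$class_weights) != 6)
    stopf("class_weights must have six entries")
  if (cfg$size < 32) stopf("scene size below 32 pixels is not supported")
  if (cfg$n_trees < 1 || cfg$m_try < 1 || cfg$m_try > 17)
    stopf("invalid classifier spec")
  structure(cfg, class = "pc_config")
}

#' @rdname pipeline_config
#' @param cfg A `pc_config`.
#' @param path YAML path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' Run the full pipeline on a synthetic scene
#'
#' Executes simulate -> cloud screening -> percentile composite ->
#' radar statistics -> 17-band feature stack -> stratified split ->
#' random forest -> prediction -> majority filter -> error matrix ->
#' accuracy -> error-adjusted areas -> zonal accounting, writing every
#' tabular artifact as CSV plus a YAML log (configuration, its hash,
#' seeds, stage timings and pixel/sample counts) under `cfg$out_dir`.
#' Re-running with the same configuration reproduces all numeric outputs
#' exactly.
#'
#' @param cfg A `pc_config` from [pipeline_config()].
#' @param keep_rasters Keep the raster intermediates in the returned
#'   list (default TRUE).
#' @return Invisibly, a list with the scene, feature stack, maps,
#'   samples, error matrix, accuracy, area estimates, truth comparison
#'   and zonal tables.
#' @export
run_pipeline <- function(cfg, keep_rasters = TRUE) {
  stopifnot(inherits(cfg, "pc_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list(config = unclass(cfg), config_hash = rlang::hash(unclass(cfg)),
              stages = list())
  tic <- function() proc.time()[["elapsed"]]
  stamp <- function(stage, t0, ...) {
    log$stages[[stage]] <<- c(list(seconds = round(tic() - t0, 2)), list(...))
  }

  t0 <- tic()
  scene <- simulate_scene(size = cfg$size, n_optical = cfg$n_optical,
                          n_sar = cfg$n_sar,
                          cloud_fraction = cfg$cloud_fraction,
                          patch_scale = cfg$patch_scale,
                          class_weights = cfg$class_weights,
                          n_concessions = cfg$n_concessions,
                          n_reference_plots = cfg$n_reference_plots,
                          seed = cfg$seed)
  stamp("simulate", t0, pixels = cfg$size^2)

  t0 <- tic()
  rule <- cloud_rule(blue_threshold = cfg$blue_threshold,
                     swir_threshold = cfg$swir_threshold,
                     cirrus_threshold = cfg$cirrus_threshold)
  masks <- lapply(seq_along(scene$optical$dates), function(d)
    detect_clouds(scene$optical$bands[[d]], qa = scene$optical$qa[[d]],
                  rule = rule))
  comp <- percentile_mean_composite(scene$optical, masks,
                                    p_lo = cfg$p_lo, p_hi = cfg$p_hi,
                                    min_obs = cfg$min_obs)
  sar <- sar_temporal_stats(scene$sar)
  stamp("composite", t0,
        median_valid_obs = stats::median(as.vector(valid_obs(comp))))

  t0 <- tic()
  nd <- ndvi(comp)
  tex <- moving_sd(nd, window = 5)
  sl <- slope(scene$dem)
  stack <- build_feature_stack(comp, nd, tex, sar, sl, out_res = cfg$out_res)
  stamp("features", t0, layers = dim(stack$values)[3])

  t0 <- tic()
  samples <- extract_reference_pixels(scene$reference_polygons, stack)
  samples <- split_reference(samples, fraction = cfg$split_fraction,
                             seed = cfg$split_seed)
  model <- train_classifier(samples[samples$role == "train", ],
                            n_trees = cfg$n_trees, m_try = cfg$m_try,
                            seed = cfg$model_seed)
  stamp("train", t0, n_train = sum(samples$role == "train"),
        n_test = sum(samples$role == "test"))

  t0 <- tic()
  map_raw <- predict_map(model, stack)
  map <- majority_filter(map_raw, window = 3)
  truth20 <- aggregate_modal(scene$truth, round(cfg$out_res / scene$truth$res))
  agree <- mean(map$values == truth20$values, na.rm = TRUE)
  agree_raw <- mean(map_raw$values == truth20$values, na.rm = TRUE)
  stamp("predict_filter", t0, agreement_filtered = round(agree, 4),
        agreement_unfiltered = round(agree_raw, 4))

  t0 <- tic()
  pixel_area <- (cfg$out_res / 100)^2  # ha per pixel
  em <- error_matrix(samples[samples$role == "test", ], map, pixel_area)
  acc <- accuracy_metrics(em)
  est <- error_adjusted_areas(em, z = cfg$z)
  # the estimand is the composition of the mapped region, so the truth
  # benchmark counts only pixels the map classifies
  true_counts <- tabulate(truth20$values[!is.na(map$values)], nbins = 6)
  truth_tbl <- tibble(class_id = 1:6, class_name = lc_classes()$class_name,
                      true_area_ha = true_counts * pixel_area)
  stamp("assess", t0, overall_accuracy = round(acc$overall, 4))

  t0 <- tic()
  zonal <- zonal_class_areas(map, scene$zones, pixel_area)
  conc <- kind_class_areas(map, scene$zones, pixel_area, kind = "concession")
  shares <- concession_shares(conc)
  stamp("zonal", t0, n_zones = nrow(scene$zones))

  utils::write.csv(samples, file.path(cfg$out_dir, "samples.csv"),
                   row.names = FALSE)
  write_error_matrix_csv(em, file.path(cfg$out_dir, "error_matrix.csv"))
  utils::write.csv(acc$per_class, file.path(cfg$out_dir, "accuracy.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(est),
                   file.path(cfg$out_dir, "area_estimates.csv"),
                   row.names = FALSE)
  utils::write.csv(truth_tbl, file.path(cfg$out_dir, "true_areas.csv"),
                   row.names = FALSE)
  utils::write.csv(zonal, file.path(cfg$out_dir, "zonal_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(shares, file.path(cfg$out_dir, "concession_shares.csv"),
                   row.names = FALSE)
  yaml::write_yaml(log, file.path(cfg$out_dir, "log.yaml"))

  res <- list(config = cfg, samples = samples, model = model,
              error_matrix = em, accuracy = acc, area_estimates = est,
              true_areas = truth_tbl, agreement_filtered = agree,
              agreement_unfiltered = agree_raw, zonal = zonal,
              concession_areas = conc, concession_shares = shares,
              log = log)
  if (keep_rasters) {
    res$scene <- scene
    res$composite <- comp
    res$stack <- stack
    res$map_raw <- map_raw
    res$map <- map
    res$truth20 <- truth20
  }
  invisible(res)
}
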