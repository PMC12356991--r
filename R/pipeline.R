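#' Experiment configuration
#'
#' Bundles every stage's settings for [run_experiment()].  The master seed
#' deterministically derives all per-stage seeds.  Per-image acquisition
#' conditions (AEC-like mean signal, parenchymal texture RMS) are drawn
#' uniformly from the configured ranges, which is what spreads detectability
#' across the cohort.
#'
#' @param preset preset name (`"A"` or `"B"`) or a [system_preset()].
#' @param n_images cohort size.
#' @param shape image dimensions in pixels.
#' @param contrast insertion contrast lambda (default 0.08).
#' @param n_calcs,calc_diameter,cluster_window cluster geometry forwarded to
#'   [generate_cluster_mask()] (counts, micrometers, millimeters).
#' @param mean_signal_range,texture_rms_range per-image acquisition ranges
#'   (digital units).
#' @param texture_exponent power-spectrum exponent beta.
#' @param dose_fraction,blur_fraction proportions of images degraded.
#' @param dose_level dose fraction gamma for the dose-reduced images.
#' @param n_readers virtual readers per image.
#' @param n_per_class test ROIs per class per image.
#' @param n_train_absent,n_train_present per-reader training draw sizes.
#' @param target_band internal-noise calibration AUC band.
#' @param n_calib_images ensemble size for internal-noise calibration.
#' @param n_pool_images images contributing training ROIs to the reader pool.
#' @param features a [feature_config()].
#' @param outer_folds,inner_folds cross-validation plan.
#' @param consensus_threshold consensus proportion (0.1 for cohorts with
#'   degradations, 0.5 otherwise).
#' @param mlp_args list of [mlp()] overrides.
#' @param seed master seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(preset = "A", n_images = 300, shape = c(320, 320),
                       contrast = 0.08,
                       n_calcs = 5, calc_diameter = 200, cluster_window = 10,
                       mean_signal_range = c(300, 900),
                       texture_rms_range = c(20, 100),
                       texture_exponent = 3,
                       dose_fraction = 0.10, blur_fraction = 0.10,
                       dose_level = 0.75,
                       n_readers = 30, n_per_class = 200,
                       n_train_absent = 1500, n_train_present = 500,
                       target_band = c(0.75, 0.80),
                       n_calib_images = 50, n_pool_images = 40,
                       features = feature_config_reduced(),
                       outer_folds = 10, inner_folds = 5,
                       consensus_threshold = 0.1,
                       mlp_args = list(), seed = 1) {
  if (is.character(preset)) preset <- default_preset(preset)
  structure(as.list(environment()), class = "run_config")
}

# Deterministic per-stage seed derived from (master seed, stage name).
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((as.numeric(seed) * 20011 + h * 7919) %% 2000000000)
}

#' Run the end-to-end detectability-prediction experiment
#'
#' Generate -> degrade -> score (CHO) -> extract -> select -> regress, with
#' every tabular intermediate persisted under `workdir` (manifest, scores,
#' features, selection, report) plus a JSONL log of stage timings, seeds and
#' counts.  With `write_images = TRUE` the degraded rasters are written as
#' 16-bit TIFFs as well.
#'
#' @param config a [run_config()].
#' @param workdir writable output directory (created if needed).
#' @param write_images also persist per-image rasters (default FALSE).
#' @return list of class `mammoiq_experiment`: `report` (a `cv_report`),
#'   `scores`, `selection`, `calibration`, `manifest`, `paths`.
#' @export
run_experiment <- function(config, workdir, write_images = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(workdir, "log.jsonl")
  if (file.exists(logfile)) unlink(logfile)
  log_stage <- function(stage, seed, n, t0) {
    line <- jsonlite::toJSON(list(stage = stage, seed = seed, n = n,
                                  seconds = round(as.numeric(Sys.time()) - t0, 2)),
                             auto_unbox = TRUE)
    cat(line, "\n", sep = "", file = logfile, append = TRUE)
  }
  preset <- config$preset

  # -- simulate --------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  s_man <- stage_seed(config$seed, "manifest")
  manifest <- generate_manifest(config$n_images, preset,
                                config$dose_fraction, config$blur_fraction,
                                seed = s_man)
  set.seed(stage_seed(config$seed, "acquisition"))
  mean_sig <- stats::runif(config$n_images, config$mean_signal_range[1],
                           config$mean_signal_range[2])
  tex_rms <- stats::runif(config$n_images, config$texture_rms_range[1],
                          config$texture_rms_range[2])
  images <- lapply(seq_len(config$n_images), function(i)
    generate_background(preset, config$shape,
                        texture_exponent = config$texture_exponent,
                        mean_signal = mean_sig[i], texture_rms = tex_rms[i],
                        seed = manifest$seed[i], id = manifest$id[i]))
  utils::write.csv(manifest, file.path(workdir, "manifest.csv"),
                   row.names = FALSE)
  log_stage("simulate", s_man, config$n_images, t0)

  # -- degrade ---------------------------------------------------------------
  # The scoring protocol inserts the lesion first and degrades afterwards, so
  # originals are kept and degradation enters twice: as a per-patch transform
  # at scoring, and as an image-level transform for feature extraction.
  t0 <- as.numeric(Sys.time())
  s_deg <- stage_seed(config$seed, "degrade")
  kernel <- make_motion_kernel()
  dpar <- dose_params(config$dose_level, gain = preset$gain,
                      offset = preset$offset,
                      electronic_sigma = preset$electronic_sigma)
  degrade_patch_fn <- function(i) {
    switch(manifest$tag[i],
           dose75 = function(patch, k)
             dose_transform(patch, dpar, seed = s_deg + 131L * i + k),
           blur = function(patch, k) conv2_reflect(patch, kernel$weights),
           none = NULL)
  }
  degraders <- lapply(seq_len(config$n_images), degrade_patch_fn)
  degrade_image <- function(i) {
    switch(manifest$tag[i],
           dose75 = reduce_dose(images[[i]], dpar, seed = s_deg + i),
           blur = motion_blur(images[[i]], kernel),
           none = images[[i]])
  }
  if (write_images)
    for (i in seq_len(config$n_images))
      write_raw_image(degrade_image(i), file.path(workdir, manifest$path[i]))
  log_stage("degrade", s_deg, sum(manifest$tag != "none"), t0)

  # -- score -----------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  s_sc <- stage_seed(config$seed, "score")
  lesion <- generate_cluster_mask(preset, n_calcs = config$n_calcs,
                                  calc_diameter = config$calc_diameter,
                                  window = config$cluster_window,
                                  seed = stage_seed(config$seed, "cluster"))
  channels <- cluster_channels(make_lg_channels(preset$roi_side), lesion)
  set.seed(s_sc)
  pool_idx <- sample.int(config$n_images, min(config$n_pool_images,
                                              config$n_images))
  pool <- build_roi_pool(images[pool_idx], lesion, config$contrast, channels,
                         seed = s_sc + 1L,
                         degrade_patch_list = degraders[pool_idx])
  calib_idx <- seq_len(min(config$n_calib_images, config$n_images))
  calib <- calibrate_internal_noise(images[calib_idx], lesion,
                                    config$contrast, channels = channels,
                                    pool = pool,
                                    target_low = config$target_band[1],
                                    target_high = config$target_band[2],
                                    n_train_absent = config$n_train_absent,
                                    n_train_present = config$n_train_present,
                                    seed = s_sc + 2L,
                                    degrade_patch_list = degraders[calib_idx])
  scores <- score_ensemble(images, lesion, config$contrast, pool,
                           n_readers = config$n_readers,
                           n_per_class = config$n_per_class,
                           internal_sigma = calib$internal_sigma,
                           n_train_absent = config$n_train_absent,
                           n_train_present = config$n_train_present,
                           seed = s_sc + 3L,
                           degrade_patch_list = degraders)
  utils::write.csv(scores, file.path(workdir, "scores.csv"),
                   row.names = FALSE)
  log_stage("score", s_sc, nrow(scores), t0)

  # -- extract ---------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  feats <- extract_feature_table(lapply(seq_len(config$n_images),
                                        degrade_image),
                                 config$features)
  feats$auc_mean <- scores$auc_mean
  feats$tag <- manifest$tag
  utils::write.csv(feats, file.path(workdir, "features.csv"),
                   row.names = FALSE)
  log_stage("extract", NA, ncol(feats) - 3L, t0)

  # -- select ----------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  s_cv <- stage_seed(config$seed, "cv")
  plan <- make_cv_plan(config$n_images, config$outer_folds,
                       config$inner_folds, seed = s_cv)
  fcols <- setdiff(names(feats), c("id", "auc_mean", "tag"))
  selection <- nested_cv_select(feats[fcols], feats$auc_mean, plan,
                                threshold = config$consensus_threshold)
  jsonlite::write_json(list(threshold = selection$threshold,
                            frequency = as.list(selection$frequency),
                            consensus = selection$consensus,
                            subsets = selection$subsets),
                       file.path(workdir, "selection.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage("select", s_cv, length(selection$consensus), t0)

  # -- regress ---------------------------------------------------------------
  t0 <- as.numeric(Sys.time())
  s_reg <- stage_seed(config$seed, "regress")
  report <- run_outer_cv(feats[fcols], feats$auc_mean, selection, plan,
                         mlp_args = config$mlp_args, seed = s_reg)
  utils::write.csv(report$per_fold, file.path(workdir, "report.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(mean = as.list(report$mean),
                            sd = as.list(report$sd)),
                       file.path(workdir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$predictions,
                   file.path(workdir, "predictions.csv"), row.names = FALSE)
  log_stage("regress", s_reg, nrow(report$per_fold), t0)

  structure(list(report = report, scores = scores, selection = selection,
                 calibration = calib, manifest = manifest,
                 paths = list(workdir = workdir)),
            class = "mammoiq_experiment")
}

#' @export
print.mammoiq_experiment <- function(x, ...) {
  cat(sprintf("<mammoiq_experiment> %d images, internal sigma %.3g (ensemble AUC %.3f)\n",
              nrow(x$manifest), x$calibration$internal_sigma,
              x$calibration$achieved_auc))
  print(x$report)
  invisible(x)
}
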