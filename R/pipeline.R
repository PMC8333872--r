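#' Default pipeline configuration
#'
#' Nested configuration for the simulate -> preprocess -> train -> evaluate
#' pipeline. Defaults reproduce the reference study conditions: the
#' 2560 x 1440 (595 x 335 mm) screen viewed at 500 mm, a serpentine
#' calibration path run under three head poses (yaw -20/0/+20 degrees) with
#' 1-px landmark noise and a 2.7% blink rate, likelihood filtering at 0.7,
#' 530-px spatial balancing, a 50/25/25 split, and the 14-200-2 network
#' trained with SGD (lr 0.03 halved every 2000 epochs, momentum 0.6,
#' batch 4, best-validation checkpoint at 10-epoch resolution). The path
#' speed (475 px/s) makes the three poses total ~3,500 frames, the scale of
#' the reference dataset.
#'
#' A single master `seed` deterministically derives the per-stage seeds via
#' [derive_seed()].
#'
#' @param seed Integer master seed.
#' @param out_dir Directory where stage artifacts are written.
#' @param max_epochs Training epochs; default 15000.
#' @return A nested list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 1L, out_dir = "gazekit-run",
                                    max_epochs = 15000) {
  structure(list(
    geometry = list(screen_width_mm = 595, screen_height_mm = 335,
                    screen_width_px = 2560, screen_height_px = 1440,
                    viewing_distance_mm = 500),
    simulation = list(n_lines = 5, fps = 30, slow_factor = 0.4,
                      fast_factor = 1.6, margin_px = 50,
                      speed_px_per_s = 475, noise_sd_px = 1,
                      blink_probability = 0.027,
                      poses_yaw_deg = c(-20, 0, 20),
                      focal_length_px = 1360,
                      frame_width_px = 600, frame_height_px = 500),
    preprocess = list(likelihood_threshold = 0.7, balance_edge_px = 530,
                      fractions = c(0.50, 0.25, 0.25), norm_constant = 600),
    training = list(learning_rate0 = 0.03, momentum = 0.6,
                    halve_every_epochs = 2000, batch_size = 4,
                    max_epochs = max_epochs, validate_every_epochs = 10,
                    n_hidden = 200),
    evaluation = list(region_edge_px = 160, hist_bins = 30,
                      kde_grid_n = 400, kde_levels = 12,
                      regression_mode = "region"),
    seed = as.integer(seed), out_dir = out_dir
  ), class = "pipeline_config")
}

config_geometry <- function(config) {
  g <- config$geometry
  screen_geometry(g$screen_width_mm, g$screen_height_mm,
                  g$screen_width_px, g$screen_height_px,
                  g$viewing_distance_mm)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @return `path` (writer) or the restored `pipeline_config` (reader).
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_pipeline_config()
  for (blk in names(base)) {
    if (is.list(base[[blk]]) && !is.null(cfg[[blk]])) {
      base[[blk]][names(cfg[[blk]])] <- cfg[[blk]]
    } else if (!is.null(cfg[[blk]])) {
      base[[blk]] <- cfg[[blk]]
    }
  }
  base$seed <- as.integer(base$seed)
  base
}

stamp <- function(config) {
  list(config_hash = rlang::hash(unclass(config)), seed = config$seed)
}

require_artifact <- function(path, stage) {
  if (!file.exists(path)) {
    stop(sprintf("missing artifact '%s': run %s first", path, stage))
  }
  path
}

#' Pipeline stages
#'
#' Each stage reads its inputs from, and writes its artifacts to,
#' `config$out_dir`, stamped with the config hash and master seed, and is
#' deterministic given identical inputs and seeds. `run_all()` chains the
#' four stages. Stage bookkeeping (frames simulated, removed by the filter,
#' per-tile balancing counts, split sizes) is logged via `message()`.
#'
#' @param config A [default_pipeline_config()].
#' @return `run_simulate()`: paths of the landmark/truth CSVs.
#'   `run_preprocess()`: the preprocessing report. `run_train()`: the
#'   training result (best parameters and trace). `run_evaluate()` and
#'   `run_all()`: the [evaluate_gaze()] report.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
run_simulate <- function(config = default_pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  geom <- config_geometry(config)
  sm <- config$simulation
  path <- generate_calibration_path(geom, sm$n_lines, sm$fps, sm$slow_factor,
                                    sm$fast_factor, sm$margin_px,
                                    sm$speed_px_per_s)
  cam <- camera_model(geom, sm$focal_length_px, sm$frame_width_px,
                      sm$frame_height_px)
  cfg <- simulation_config(noise_sd_px = sm$noise_sd_px,
                           blink_probability = sm$blink_probability,
                           fps = sm$fps,
                           seed = derive_seed(config$seed, "simulate"),
                           poses = lapply(sm$poses_yaw_deg,
                                          function(y) head_pose(yaw = y)))
  sess <- simulate_session(path, face_model(), cam, cfg)
  lm_path <- file.path(config$out_dir, "landmarks.csv")
  truth_path <- file.path(config$out_dir, "targets.csv")
  write_dlc_csv(sess$landmarks, lm_path)
  write_truth_csv(sess$truth, truth_path)
  write_pipeline_config(config, file.path(config$out_dir, "config.yaml"))
  jsonlite::write_json(c(stamp(config),
                         list(n_frames = nrow(sess$landmarks),
                              n_poses = length(cfg$poses),
                              frames_per_pose = nrow(path))),
                       file.path(config$out_dir, "simulate_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  message(sprintf("simulate: %d frames (%d poses x %d)",
                  nrow(sess$landmarks), length(cfg$poses), nrow(path)))
  invisible(list(landmarks = lm_path, truth = truth_path))
}

#' @rdname pipeline
#' @export
run_preprocess <- function(config = default_pipeline_config()) {
  lm_path <- require_artifact(file.path(config$out_dir, "landmarks.csv"),
                              "run_simulate()")
  truth_path <- require_artifact(file.path(config$out_dir, "targets.csv"),
                                 "run_simulate()")
  pp <- config$preprocess
  res <- preprocess_session(read_dlc_csv(lm_path), read_truth_csv(truth_path),
                            config_geometry(config),
                            pp$likelihood_threshold, pp$balance_edge_px,
                            pp$fractions, pp$norm_constant,
                            seed = config$seed)
  utils::write.csv(res$dataset, file.path(config$out_dir, "dataset.csv"),
                   row.names = FALSE)
  jsonlite::write_json(c(stamp(config), res$report),
                       file.path(config$out_dir, "preprocess_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  message(sprintf(paste0("preprocess: %d frames in, %d removed by filter ",
                         "(%.1f%%), %d after balancing (min tile %d); ",
                         "split %s"),
                  res$report$n_input, res$report$n_removed_by_filter,
                  100 * res$report$fraction_removed, res$report$n_balanced,
                  res$report$min_tile_count,
                  paste(unlist(res$report$split_sizes), collapse = "/")))
  invisible(res$report)
}

read_dataset <- function(config) {
  path <- require_artifact(file.path(config$out_dir, "dataset.csv"),
                           "run_preprocess()")
  ds <- utils::read.csv(path, check.names = FALSE)
  ds$split <- factor(ds$split, levels = c("train", "validation", "test"))
  ds
}

#' @rdname pipeline
#' @export
run_train <- function(config = default_pipeline_config()) {
  ds <- read_dataset(config)
  tr <- config$training
  geom <- config_geometry(config)
  cfg <- train_config(tr$learning_rate0, tr$momentum, tr$halve_every_epochs,
                      tr$batch_size, tr$max_epochs,
                      tr$validate_every_epochs,
                      seed = derive_seed(config$seed, "train"),
                      target_scale = geom$width_px, n_hidden = tr$n_hidden)
  fc <- feature_column_names()
  xt <- as.matrix(ds[ds$split == "train", fc])
  yt <- as.matrix(ds[ds$split == "train", c("target_x_px", "target_y_px")]) /
    cfg$target_scale
  xv <- as.matrix(ds[ds$split == "validation", fc])
  yv <- as.matrix(ds[ds$split == "validation",
                     c("target_x_px", "target_y_px")]) / cfg$target_scale
  fit <- train_gaze_mlp(xt, yt, xv, yv, cfg)
  write_gaze_mlp(fit$params, file.path(config$out_dir, "model.json"),
                 meta = c(stamp(config),
                          list(target_scale = cfg$target_scale,
                               best_epoch = fit$best_epoch,
                               best_val_loss = fit$best_val_loss,
                               max_epochs = cfg$max_epochs)))
  utils::write.csv(fit$trace, file.path(config$out_dir, "trace.csv"),
                   row.names = FALSE)
  message(sprintf("train: %d epochs, best validation at epoch %d (loss %.3g)",
                  cfg$max_epochs, fit$best_epoch, fit$best_val_loss))
  invisible(fit)
}

#' @rdname pipeline
#' @export
run_evaluate <- function(config = default_pipeline_config()) {
  model_path <- require_artifact(file.path(config$out_dir, "model.json"),
                                 "run_train()")
  ds <- read_dataset(config)
  params <- read_gaze_mlp(model_path)
  meta <- attr(params, "meta")
  geom <- config_geometry(config)
  test <- ds[ds$split == "test", , drop = FALSE]
  est <- predict_gaze(params, as.matrix(test[feature_column_names()]),
                      target_scale = meta$target_scale)
  ev <- config$evaluation
  report <- evaluate_gaze(est,
                          as.matrix(test[c("target_x_px", "target_y_px")]),
                          geom, ev$hist_bins, ev$region_edge_px,
                          ev$kde_grid_n, ev$kde_levels, ev$regression_mode)
  write_error_report(report, file.path(config$out_dir, "report"))
  message(sprintf("evaluate: n = %d test samples, median error %.3f dva",
                  report$summaries$n, report$summaries$median_dva))
  invisible(report)
}

#' @rdname pipeline
#' @export
run_all <- function(config = default_pipeline_config()) {
  run_simulate(config)
  run_preprocess(config)
  run_train(config)
  run_evaluate(config)
}
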