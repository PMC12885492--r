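#' Run the full synthetic calibration study in memory
#'
#' End-to-end orchestration of the emulated blood-loop study: simulate the
#' paired dataset, split samples into calibration and validation strata by
#' day, compute cross-sensor scaling on the calibration windows, build the
#' feature library, fit the hemoglobin and saturation models on the pooled
#' calibration data of both sensors, predict on every window (saturation
#' driven by the predicted hemoglobin), and compute agreement reports per
#' sensor, split, and parameter. All randomness flows from the single
#' `seed` through named sub-streams (simulation, split, CV folds), so a
#' run is fully reproducible.
#'
#' @param seed Master integer seed.
#' @param protocol An [experiment_protocol()]; its seed is overridden by
#'   `seed`. Default: the standard 86-sample, 7-day protocol.
#' @param constants,profiles Forward-model configuration.
#' @param split_fraction Calibration fraction of the day-stratified split.
#' @param cv_folds,mixing_grid,lambda_grid Passed to [fit_hgb_model()].
#' @param bin_halfwidth,min_bin_size Passed to [fit_so2_model()].
#' @return List of class `oximcal_run` with elements `sim`, `split`,
#'   `scaling`, `bundle`, `predictions`, `reports` (tidy data frame),
#'   `report_objects` (list of `agreement_report`s), and `seed`.
#' @export
run_pipeline <- function(seed = 1L, protocol = NULL,
                         constants = optical_constants(),
                         profiles = default_sensor_profiles(),
                         split_fraction = 0.5, cv_folds = 5L,
                         mixing_grid = c(0.1, 0.5, 0.9), lambda_grid = NULL,
                         bin_halfwidth = 0.5, min_bin_size = 3L) {
  if (is.null(protocol)) protocol <- experiment_protocol()
  protocol$seed <- as.integer(seed)
  sim <- simulate_experiment(protocol, constants, profiles)
  split <- split_calibration_validation(sim$bloodgas,
                                        fraction = split_fraction,
                                        seed = seed)
  cal_windows <- sim$windows[sim$windows$sample_id %in% split$calibration, ,
                             drop = FALSE]
  scaling <- compute_sensor_scaling(cal_windows)
  feats <- build_features(sim$windows, scaling)
  bg <- sim$bloodgas[match(feats$sample_id, sim$bloodgas$sample_id), ]
  feats$split <- ifelse(feats$sample_id %in% split$calibration,
                        "calibration", "validation")
  cal <- feats$split == "calibration"

  hgb_model <- fit_hgb_model(feats[cal, , drop = FALSE], bg$hgb_gdl[cal],
                             cv_folds = cv_folds, mixing_grid = mixing_grid,
                             lambda_grid = lambda_grid, seed = seed)
  so2_model <- fit_so2_model(feats[cal, , drop = FALSE], bg$so2_pct[cal],
                             hgb_for_binning = bg$hgb_gdl[cal],
                             bin_halfwidth = bin_halfwidth,
                             min_bin_size = min_bin_size)
  bundle <- calibration_bundle(
    hgb_model, so2_model, scaling,
    provenance = list(seed = as.integer(seed),
                      split = sprintf("stratified by day, fraction %.3f",
                                      split_fraction),
                      calibration_ids = split$calibration,
                      validation_ids = split$validation))

  hgb_pred <- suppressWarnings(predict_hgb(feats, hgb_model))
  so2_pred <- predict_so2(feats, hgb_pred, so2_model)
  predictions <- data.frame(
    sample_id = feats$sample_id, sensor_id = feats$sensor_id,
    day_id = feats$day_id, split = feats$split,
    hgb_pred_gdl = hgb_pred, so2_pred_pct = as.numeric(so2_pred),
    so2_clamped = attr(so2_pred, "clamped"),
    hgb_ref_gdl = bg$hgb_gdl, so2_ref_pct = bg$so2_pct)

  report_objects <- list()
  rows <- list()
  for (sid in sort(unique(predictions$sensor_id))) {
    for (sp in c("calibration", "validation")) {
      sub <- predictions[predictions$sensor_id == sid &
                           predictions$split == sp, , drop = FALSE]
      for (param in c("hgb", "so2")) {
        rep <- agreement_report(
          predicted = if (param == "hgb") sub$hgb_pred_gdl else sub$so2_pred_pct,
          reference = if (param == "hgb") sub$hgb_ref_gdl else sub$so2_ref_pct,
          n_predictors = if (param == "hgb") 8L else 4L,
          day_id = sub$day_id, sensor_id = sid, split = sp,
          parameter = param)
        report_objects[[sprintf("sensor%s_%s_%s", sid, sp, param)]] <- rep
        rows[[length(rows) + 1L]] <- as.data.frame(rep)
      }
    }
  }
  structure(list(sim = sim, split = split, scaling = scaling,
                 bundle = bundle, predictions = predictions,
                 reports = do.call(rbind, rows),
                 report_objects = report_objects,
                 seed = as.integer(seed)),
            class = "oximcal_run")
}

#' @export
print.oximcal_run <- function(x, ...) {
  cat(sprintf("Synthetic calibration study (seed %d): %d samples, %d sensors\n",
              x$seed, nrow(x$sim$bloodgas),
              length(unique(x$sim$windows$sensor_id))))
  cat(sprintf("  split: %d calibration / %d validation\n",
              length(x$split$calibration), length(x$split$validation)))
  print(x$reports, row.names = FALSE, digits = 4)
  invisible(x)
}

protocol_from_overrides <- function(overrides) {
  args <- overrides[names(overrides) %in% names(formals(experiment_protocol))]
  do.call(experiment_protocol, args)
}

#' Simulate a dataset and write it to disk
#'
#' Writes the window CSV (`sample_id,sensor_id,day_id,i680,i850,n_points`),
#' the blood-gas CSV (`sample_id,day_id,timestamp_s,hgb_gdl,so2_pct`),
#' optionally the raw 20 Hz intensity CSV, and a config-snapshot sidecar
#' JSON recording the seed and protocol.
#'
#' @param out_dir Writable output directory (created if absent).
#' @param seed Master seed.
#' @param protocol_overrides Named list overriding [experiment_protocol()]
#'   defaults (e.g. `list(samples_total = 10)`).
#' @param constants,profiles Forward-model configuration.
#' @param emit_raw Also write `intensity_raw.csv` (default `FALSE`).
#' @return Named list of output paths, invisibly.
#' @export
cmd_simulate <- function(out_dir, seed = 1L, protocol_overrides = list(),
                         constants = optical_constants(),
                         profiles = default_sensor_profiles(),
                         emit_raw = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    stop(sprintf("I/O error: cannot create output directory %s", out_dir),
         call. = FALSE)
  }
  protocol <- protocol_from_overrides(protocol_overrides)
  protocol$seed <- as.integer(seed)
  sim <- simulate_experiment(protocol, constants, profiles)
  paths <- list(windows = file.path(out_dir, "windows.csv"),
                bloodgas = file.path(out_dir, "bloodgas.csv"),
                config = file.path(out_dir, "simulate_config.json"))
  write_csv_plain(sim$windows, paths$windows)
  write_csv_plain(sim$bloodgas, paths$bloodgas)
  if (emit_raw) {
    paths$raw <- file.path(out_dir, "intensity_raw.csv")
    write_csv_plain(emit_raw_intensity(sim), paths$raw)
  }
  write_config_snapshot(
    list(command = "simulate", seed = as.integer(seed),
         protocol = unclass(protocol), constants = unclass(constants),
         profiles = lapply(profiles, unclass),
         outputs = lapply(paths[names(paths) != "config"], basename)),
    paths$config)
  invisible(paths)
}

join_windows_bloodgas <- function(windows, bloodgas) {
  orphans <- setdiff(windows$sample_id, bloodgas$sample_id)
  if (length(orphans) > 0L) {
    stop(sprintf(
      "data-integrity error: window sample_id(s) missing from blood-gas table: %s",
      paste(sort(unique(orphans)), collapse = ", ")), call. = FALSE)
  }
  bloodgas[match(windows$sample_id, bloodgas$sample_id), , drop = FALSE]
}

#' Calibrate from window and blood-gas CSVs and write the bundle
#'
#' Reads the window and blood-gas tables, checks that every window joins a
#' blood-gas row on `sample_id`, performs the day-stratified split, fits
#' the cross-sensor scaling and both models on the calibration stratum, and
#' writes the calibration bundle JSON (split recorded in its provenance)
#' plus a config snapshot.
#'
#' @param windows_csv,bloodgas_csv Input CSV paths.
#' @param out_bundle Output bundle JSON path.
#' @param seed Master seed (split and CV sub-streams).
#' @param split_fraction Calibration fraction.
#' @param cv_folds,mixing_grid,lambda_grid Passed to [fit_hgb_model()].
#' @param bin_halfwidth,min_bin_size Passed to [fit_so2_model()].
#' @return The `calibration_bundle`, invisibly.
#' @export
cmd_calibrate <- function(windows_csv, bloodgas_csv, out_bundle, seed = 1L,
                          split_fraction = 0.5, cv_folds = 5L,
                          mixing_grid = c(0.1, 0.5, 0.9), lambda_grid = NULL,
                          bin_halfwidth = 0.5, min_bin_size = 3L) {
  windows <- read_windows_csv(windows_csv)
  bloodgas <- read_bloodgas_csv(bloodgas_csv)
  join_windows_bloodgas(windows, bloodgas)
  split <- split_calibration_validation(bloodgas, fraction = split_fraction,
                                        seed = seed)
  cal_windows <- windows[windows$sample_id %in% split$calibration, ,
                         drop = FALSE]
  scaling <- compute_sensor_scaling(cal_windows)
  feats <- build_features(windows, scaling)
  bg <- join_windows_bloodgas(windows, bloodgas)
  cal <- feats$sample_id %in% split$calibration
  hgb_model <- fit_hgb_model(feats[cal, , drop = FALSE], bg$hgb_gdl[cal],
                             cv_folds = cv_folds, mixing_grid = mixing_grid,
                             lambda_grid = lambda_grid, seed = seed)
  so2_model <- fit_so2_model(feats[cal, , drop = FALSE], bg$so2_pct[cal],
                             hgb_for_binning = bg$hgb_gdl[cal],
                             bin_halfwidth = bin_halfwidth,
                             min_bin_size = min_bin_size)
  bundle <- calibration_bundle(
    hgb_model, so2_model, scaling,
    provenance = list(seed = as.integer(seed),
                      split = sprintf("stratified by day, fraction %.3f",
                                      split_fraction),
                      calibration_ids = split$calibration,
                      validation_ids = split$validation,
                      windows_csv = basename(windows_csv),
                      bloodgas_csv = basename(bloodgas_csv)))
  write_calibration_bundle(bundle, out_bundle)
  write_config_snapshot(
    list(command = "calibrate", seed = as.integer(seed),
         split_fraction = split_fraction, cv_folds = cv_folds,
         inputs = list(windows = basename(windows_csv),
                       bloodgas = basename(bloodgas_csv)),
         outputs = list(bundle = basename(out_bundle))),
    paste0(out_bundle, ".config.json"))
  invisible(bundle)
}

#' Predict hemoglobin and saturation for a window CSV
#'
#' Applies a calibration bundle to new windows: scales each sensor's
#' intensities with the bundle's factors (unknown sensors are an error),
#' predicts hemoglobin from the feature library, then saturation using the
#' predicted hemoglobin in the concentration correction. An empty input
#' yields an empty predictions file with a header and a warning.
#'
#' @param bundle Path to a bundle JSON, or a `calibration_bundle`.
#' @param windows_csv Input window CSV path.
#' @param out_csv Output CSV
#'   (`sample_id,sensor_id,hgb_pred_gdl,so2_pred_pct,so2_clamped`).
#' @return The predictions data frame, invisibly.
#' @export
cmd_predict <- function(bundle, windows_csv, out_csv) {
  if (is.character(bundle)) bundle <- read_calibration_bundle(bundle)
  stopifnot(inherits(bundle, "calibration_bundle"))
  windows <- read_windows_csv(windows_csv)
  if (nrow(windows) == 0L) {
    warning("empty intensity window file; writing empty predictions")
    out <- data.frame(sample_id = integer(), sensor_id = integer(),
                      hgb_pred_gdl = numeric(), so2_pred_pct = numeric(),
                      so2_clamped = logical())
    write_csv_plain(out, out_csv)
    return(invisible(out))
  }
  unknown <- setdiff(unique(windows$sensor_id), bundle$scalings$sensor_id)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown-sensor: sensor(s) %s absent from bundle scalings",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  feats <- build_features(windows, bundle$scalings)
  hgb <- suppressWarnings(predict_hgb(feats, bundle$hgb_model))
  so2 <- predict_so2(feats, hgb, bundle$so2_model)
  out <- data.frame(sample_id = feats$sample_id, sensor_id = feats$sensor_id,
                    hgb_pred_gdl = hgb, so2_pred_pct = as.numeric(so2),
                    so2_clamped = attr(so2, "clamped"))
  write_csv_plain(out, out_csv)
  invisible(out)
}

#' Validate predictions against blood-gas references
#'
#' Joins predictions with the blood-gas table on `sample_id`, labels each
#' row with its split (from the bundle's recorded calibration/validation
#' sample ids; rows fall back to a single `"all"` label with a warning when
#' no split information is available), and writes one agreement report per
#' (sensor, split, parameter): a tidy CSV plus a JSON document that also
#' carries the per-day MADs.
#'
#' @param predictions_csv Predictions CSV from [cmd_predict()].
#' @param bloodgas_csv Blood-gas reference CSV.
#' @param out_prefix Output prefix; writes `<prefix>.csv` and
#'   `<prefix>.json`.
#' @param bundle Optional bundle (path or object) supplying split labels.
#' @return The tidy report data frame, invisibly.
#' @export
cmd_validate <- function(predictions_csv, bloodgas_csv, out_prefix,
                         bundle = NULL) {
  preds <- read_predictions_csv(predictions_csv)
  bloodgas <- read_bloodgas_csv(bloodgas_csv)
  keep <- preds$sample_id %in% bloodgas$sample_id
  preds <- preds[keep, , drop = FALSE]
  if (nrow(preds) < 2L) {
    stop("insufficient-data: fewer than 2 joined prediction/reference rows",
         call. = FALSE)
  }
  bg <- bloodgas[match(preds$sample_id, bloodgas$sample_id), , drop = FALSE]
  if (is.character(bundle)) bundle <- read_calibration_bundle(bundle)
  if (!is.null(bundle) &&
      !is.null(bundle$provenance$calibration_ids)) {
    preds$split <- ifelse(
      preds$sample_id %in% unlist(bundle$provenance$calibration_ids),
      "calibration", "validation")
  } else {
    warning("no split information available; labelling all rows 'all'")
    preds$split <- "all"
  }
  rows <- list(); docs <- list()
  for (sid in sort(unique(preds$sensor_id))) {
    for (sp in unique(preds$split)) {
      sel <- preds$sensor_id == sid & preds$split == sp
      if (sum(sel) < 2L) next
      for (param in c("hgb", "so2")) {
        rep <- agreement_report(
          predicted = if (param == "hgb") preds$hgb_pred_gdl[sel]
                      else preds$so2_pred_pct[sel],
          reference = if (param == "hgb") bg$hgb_gdl[sel] else bg$so2_pct[sel],
          n_predictors = if (param == "hgb") 8L else 4L,
          day_id = bg$day_id[sel], sensor_id = sid, split = sp,
          parameter = param)
        rows[[length(rows) + 1L]] <- as.data.frame(rep)
        docs[[sprintf("sensor%s_%s_%s", sid, sp, param)]] <-
          c(unclass(rep)[c("sensor_id", "split", "parameter", "n", "arms",
                           "mad", "r2", "adj_r2", "bias", "loa_low",
                           "loa_high")],
            list(per_day_mad = as.list(rep$per_day_mad)))
      }
    }
  }
  tidy <- do.call(rbind, rows)
  write_csv_plain(tidy, paste0(out_prefix, ".csv"))
  jsonlite::write_json(list(schema_version = "1.0", reports = docs),
                       paste0(out_prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(tidy)
}
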