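#' Assemble a calibration bundle
#'
#' The deployable artifact of a calibration run: the fitted hemoglobin
#' model, the fitted saturation model, the per-sensor scaling factors, and
#' provenance (seed, split description, software version). Serializes to
#' and from JSON losslessly.
#'
#' @param hgb_model A fitted [fit_hgb_model()] object.
#' @param so2_model A fitted [fit_so2_model()] object.
#' @param scalings Scaling data frame from [compute_sensor_scaling()].
#' @param provenance Named list (seed, split description, free-form notes).
#' @return An object of class `calibration_bundle`.
#' @export
calibration_bundle <- function(hgb_model, so2_model, scalings,
                               provenance = list()) {
  stopifnot(inherits(hgb_model, "hgb_model"), inherits(so2_model, "so2_model"))
  stop_missing_cols(scalings, c("sensor_id", "scale680", "scale850"),
                    "scalings")
  provenance$software_version <-
    as.character(utils::packageVersion("oximcal"))
  structure(list(schema_version = "1.0", hgb_model = hgb_model,
                 so2_model = so2_model, scalings = scalings,
                 provenance = provenance),
            class = "calibration_bundle")
}

#' Write a calibration bundle to JSON
#'
#' Coefficient arrays are stored in their canonical orders (a1..a9 for the
#' hemoglobin model; m_alpha, b_alpha, m_beta, b_beta for the saturation
#' model) at full numeric precision so the bundle round-trips losslessly.
#'
#' @param bundle A [calibration_bundle()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "calibration_bundle"))
  hm <- bundle$hgb_model
  sm <- bundle$so2_model
  doc <- list(
    schema_version = bundle$schema_version,
    hgb_model = list(
      coeffs = as.numeric(hm$coeffs),
      penalty_lambda = hm$penalty_lambda, mixing = hm$mixing,
      cv_folds = hm$cv_folds,
      feature_means = as.numeric(hm$feature_means),
      feature_scales = as.numeric(hm$feature_scales),
      seed = hm$seed),
    so2_model = list(
      m_alpha = sm$m_alpha, b_alpha = sm$b_alpha,
      m_beta = sm$m_beta, b_beta = sm$b_beta,
      bin_halfwidth = sm$bin_halfwidth, min_bin_size = sm$min_bin_size,
      bin_fits = sm$bin_fits,
      alpha_fit_r2 = sm$alpha_fit_r2, beta_fit_r2 = sm$beta_fit_r2),
    scalings = bundle$scalings,
    provenance = bundle$provenance)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' Read a calibration bundle from JSON
#'
#' @param path Path to a bundle written by [write_calibration_bundle()].
#' @return A `calibration_bundle` object.
#' @export
read_calibration_bundle <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (key in c("hgb_model", "so2_model", "scalings")) {
    if (is.null(doc[[key]])) {
      stop(sprintf("format error in %s: missing key %s", path, key),
           call. = FALSE)
    }
  }
  hm <- doc$hgb_model
  hgb_model <- structure(list(
    coeffs = setNames(as.numeric(hm$coeffs), paste0("a", 1:9)),
    penalty_lambda = hm$penalty_lambda, mixing = hm$mixing,
    cv_folds = as.integer(hm$cv_folds),
    feature_means = setNames(as.numeric(hm$feature_means),
                             feature_term_names[1:8]),
    feature_scales = setNames(as.numeric(hm$feature_scales),
                              feature_term_names[1:8]),
    seed = hm$seed), class = "hgb_model")
  sm <- doc$so2_model
  so2_model <- structure(list(
    m_alpha = sm$m_alpha, b_alpha = sm$b_alpha,
    m_beta = sm$m_beta, b_beta = sm$b_beta,
    bin_halfwidth = sm$bin_halfwidth,
    min_bin_size = as.integer(sm$min_bin_size),
    bin_fits = as.data.frame(sm$bin_fits),
    alpha_fit_r2 = sm$alpha_fit_r2, beta_fit_r2 = sm$beta_fit_r2),
    class = "so2_model")
  structure(list(schema_version = doc$schema_version, hgb_model = hgb_model,
                 so2_model = so2_model,
                 scalings = as.data.frame(doc$scalings),
                 provenance = doc$provenance),
            class = "calibration_bundle")
}
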