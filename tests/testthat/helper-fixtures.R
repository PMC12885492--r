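# Shared fixtures, built in code. Expensive end-to-end runs are computed
# once per session and reused across test files.

.fixture_cache <- new.env(parent = emptyenv())

# Default study conditions: 86 samples, 7 days, 2 sensors, Hgb 6-14 g/dL,
# SO2 50-100%, log-intensity noise 0.005, BGA noise 0.1 g/dL / 0.5%.
default_run <- function(seed = 1L) {
  key <- paste0("run", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- run_pipeline(seed = seed)
  }
  .fixture_cache[[key]]
}

noiseless_run <- function(seed = 1L) {
  key <- paste0("noiseless", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- run_pipeline(
      seed = seed,
      protocol = experiment_protocol(bga_hgb_sigma = 0, bga_so2_sigma = 0),
      profiles = default_sensor_profiles(noise_sigma = 0))
  }
  .fixture_cache[[key]]
}

# A small raw-record data frame for one sensor: counts chosen so that
# pulse-normalized intensities are exactly the values given.
raw_records <- function(i680, i850, sensor_id = 1L, t0 = 0) {
  n <- length(i680) + length(i850)
  data.frame(
    timestamp_s = t0 + seq_len(n),
    sensor_id = sensor_id,
    wavelength_nm = c(rep(680, length(i680)), rep(850, length(i850))),
    adc_counts = c(i680, i850) * 10,
    pulse_number = 10L)
}

# Windows table with prescribed per-sensor intensities.
make_windows <- function(i680, i850, sensor_id, sample_id = NULL,
                         day_id = 1L) {
  if (is.null(sample_id)) sample_id <- seq_along(i680)
  data.frame(sample_id = sample_id, sensor_id = sensor_id, day_id = day_id,
             i680 = i680, i850 = i850, n_points = 1L)
}

# Manually assembled models for prediction-contract tests.
manual_hgb_model <- function(coeffs) {
  structure(list(coeffs = stats::setNames(coeffs, paste0("a", 1:9)),
                 penalty_lambda = 0, mixing = 0.5, cv_folds = 5L,
                 feature_means = numeric(8), feature_scales = rep(1, 8)),
            class = "hgb_model")
}

manual_so2_model <- function(m_alpha, b_alpha, m_beta, b_beta) {
  structure(list(m_alpha = m_alpha, b_alpha = b_alpha, m_beta = m_beta,
                 b_beta = b_beta, bin_halfwidth = 0.5, min_bin_size = 3L,
                 bin_fits = data.frame(), alpha_fit_r2 = NA, beta_fit_r2 = NA),
            class = "so2_model")
}

# Random well-conditioned 9-column term matrices (canonical column order)
# derived from random positive windows, for regression-oracle checks.
random_features <- function(n, seed) {
  set.seed(seed)
  w <- make_windows(i680 = exp(runif(n, 1, 3)), i850 = exp(runif(n, 0.5, 2)),
                    sensor_id = 1L)
  build_features(w)
}
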