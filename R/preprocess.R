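#' Normalize summed ADC counts by the programmed pulse number
#'
#' The analog front end sums a preset number of laser pulses per ADC reading
#' to raise signal-to-noise; summed counts scale linearly with the pulse
#' number up to the 16-bit ceiling of 65535. Dividing by the pulse number
#' recovers a dimensionless per-pulse intensity that is comparable across
#' pulse-number settings.
#'
#' @param adc_counts Non-negative integer vector of summed ADC counts
#'   (each at most 65535).
#' @param pulse_number Positive integer vector (1 to 127) of pulses summed
#'   per reading; recycled against `adc_counts`.
#' @return Numeric vector of per-pulse intensities, `adc_counts / pulse_number`.
#' @examples
#' normalize_by_pulse_count(65535, 127)
#' @export
normalize_by_pulse_count <- function(adc_counts, pulse_number) {
  if (any(!is.finite(pulse_number)) || any(pulse_number < 1)) {
    stop("invalid-record: pulse_number must be >= 1", call. = FALSE)
  }
  if (any(!is.finite(adc_counts)) || any(adc_counts < 0) ||
      any(adc_counts > 65535)) {
    stop("invalid-record: adc_counts must be in [0, 65535]", call. = FALSE)
  }
  adc_counts / pulse_number
}

#' Summarize one sampling window of raw records into an intensity window
#'
#' Averages the pulse-normalized intensities of all records inside one
#' sampling window (nominally one minute at 20 Hz, taken immediately before
#' a blood-gas draw), separately per wavelength.
#'
#' @param records Data frame of raw records for a single sensor with columns
#'   `sensor_id`, `wavelength_nm`, `adc_counts`, `pulse_number`.
#' @param sample_id,day_id Identifiers attached to the resulting window.
#' @return One-row data frame with columns
#'   `sample_id,sensor_id,day_id,i680,i850,n_points`; `n_points` is the
#'   smaller of the two per-wavelength record counts.
#' @export
window_average <- function(records, sample_id = NA, day_id = NA) {
  stopifnot(is.data.frame(records))
  stop_missing_cols(records, c("sensor_id", "wavelength_nm", "adc_counts",
                               "pulse_number"), "records")
  if (nrow(records) == 0L) stop("incomplete-window: no records", call. = FALSE)
  if (length(unique(records$sensor_id)) != 1L) {
    stop("window_average expects records from a single sensor", call. = FALSE)
  }
  if (!all(records$wavelength_nm %in% c(680, 850))) {
    stop("invalid-record: wavelength_nm must be 680 or 850", call. = FALSE)
  }
  norm <- normalize_by_pulse_count(records$adc_counts, records$pulse_number)
  is680 <- records$wavelength_nm == 680
  n680 <- sum(is680); n850 <- sum(!is680)
  if (n680 == 0L || n850 == 0L) {
    stop("incomplete-window: need at least one record per wavelength",
         call. = FALSE)
  }
  data.frame(sample_id = sample_id,
             sensor_id = records$sensor_id[1L],
             day_id = day_id,
             i680 = mean(norm[is680]),
             i850 = mean(norm[!is680]),
             n_points = min(n680, n850))
}

#' Slice a raw intensity stream into per-sample windows
#'
#' Matches raw records to blood-gas draws: each sample's window is the
#' `window_s` seconds of data ending at (and including) the draw timestamp,
#' i.e. readings are attributed to the nearest following blood-gas sample
#' within the window span, mirroring a protocol where intensity data are
#' collected immediately before each draw.
#'
#' @param intensity Raw intensity data frame (see [read_intensity_csv()]).
#' @param bloodgas Blood-gas data frame (see [read_bloodgas_csv()]).
#' @param window_s Window length in seconds (default 60).
#' @return Data frame of windows, one row per (sample, sensor) with data.
#' @export
windows_from_raw <- function(intensity, bloodgas, window_s = 60) {
  stop_missing_cols(intensity, c("timestamp_s", "sensor_id", "wavelength_nm",
                                 "adc_counts", "pulse_number"), "intensity")
  stop_missing_cols(bloodgas, c("sample_id", "day_id", "timestamp_s"),
                    "bloodgas")
  bg <- bloodgas[order(bloodgas$timestamp_s), , drop = FALSE]
  out <- list()
  for (sid in sort(unique(intensity$sensor_id))) {
    recs <- intensity[intensity$sensor_id == sid, , drop = FALSE]
    for (k in seq_len(nrow(bg))) {
      t1 <- bg$timestamp_s[k]
      sel <- recs$timestamp_s > t1 - window_s & recs$timestamp_s <= t1
      if (!any(sel)) next
      out[[length(out) + 1L]] <- window_average(
        recs[sel, , drop = FALSE],
        sample_id = bg$sample_id[k], day_id = bg$day_id[k])
    }
  }
  if (length(out) == 0L) {
    stop("incomplete-window: no records fall inside any sampling window",
         call. = FALSE)
  }
  do.call(rbind, out)
}

#' Compute cross-sensor intensity scaling factors
#'
#' Manufacturing differences make two sensors report different intensities
#' for the same blood; multiplicative per-wavelength scaling factors map
#' every sensor onto the cross-sensor grand mean so that a single
#' (sensor-independent) calibration curve can serve all sensors. For each
#' wavelength, `scale = grand mean of per-sensor mean intensities /
#' this sensor's mean intensity`, so scaled per-sensor means coincide.
#'
#' @param windows Window data frame (columns `sensor_id`, `i680`, `i850`).
#' @param sensor_ids Optional vector of sensor ids that must be present;
#'   a listed sensor with no windows raises a missing-sensor error.
#' @return Data frame `sensor_id,scale680,scale850`.
#' @export
compute_sensor_scaling <- function(windows, sensor_ids = NULL) {
  stop_missing_cols(windows, c("sensor_id", "i680", "i850"), "windows")
  if (any(windows$i680 <= 0) || any(windows$i850 <= 0)) {
    stop("domain error: window intensities must be positive", call. = FALSE)
  }
  present <- sort(unique(windows$sensor_id))
  if (!is.null(sensor_ids)) {
    absent <- setdiff(sensor_ids, present)
    if (length(absent) > 0L) {
      stop(sprintf("missing-sensor: no windows for sensor(s) %s",
                   paste(absent, collapse = ", ")), call. = FALSE)
    }
  }
  m680 <- tapply(windows$i680, windows$sensor_id, mean)[as.character(present)]
  m850 <- tapply(windows$i850, windows$sensor_id, mean)[as.character(present)]
  data.frame(sensor_id = present,
             scale680 = as.numeric(mean(m680) / m680),
             scale850 = as.numeric(mean(m850) / m850))
}

#' Apply per-sensor scaling factors to intensity windows
#'
#' @param windows Window data frame.
#' @param scaling Scaling data frame from [compute_sensor_scaling()].
#' @return `windows` with `i680`, `i850` multiplied by the sensor's scales.
#' @export
apply_sensor_scaling <- function(windows, scaling) {
  stop_missing_cols(scaling, c("sensor_id", "scale680", "scale850"), "scaling")
  idx <- match(windows$sensor_id, scaling$sensor_id)
  if (anyNA(idx)) {
    bad <- unique(windows$sensor_id[is.na(idx)])
    stop(sprintf("unknown-sensor: no scaling for sensor(s) %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  windows$i680 <- windows$i680 * scaling$scale680[idx]
  windows$i850 <- windows$i850 * scaling$scale850[idx]
  windows
}

# Column order of the nine-term polynomial function library. Note the
# deliberate asymmetry: the library contains ln680*R but no ln850*R term.
feature_term_names <- c("ln680_sq", "ln850_sq", "ratio_sq", "ln680", "ln850",
                        "ratio", "ln680_ln850", "ln680_ratio", "intercept")

#' Build the nine-term log-intensity feature library
#'
#' From scaled window intensities computes `ln680 = ln(i680)`,
#' `ln850 = ln(i850)` and their ratio `R = ln680 / ln850`, then expands the
#' polynomial function library used by the hemoglobin model, in the fixed
#' order `[ln680^2, ln850^2, R^2, ln680, ln850, R, ln680*ln850, ln680*R, 1]`.
#' There is intentionally no `ln850*R` cross term.
#'
#' @param windows Window data frame (already scaled, or pass `scaling`).
#' @param scaling Optional scaling data frame applied first via
#'   [apply_sensor_scaling()]. The ratio is always computed from scaled
#'   intensities so one calibration serves all sensors.
#' @param eps_denominator Guard on `|ln850|`; windows with scaled
#'   `i850` within `exp(+-eps)` of 1 raise a degenerate-denominator error.
#' @return Data frame carrying the window identifiers, `ln680`, `ln850`,
#'   `ratio`, and the nine term columns.
#' @export
build_features <- function(windows, scaling = NULL, eps_denominator = 1e-6) {
  if (!is.null(scaling)) windows <- apply_sensor_scaling(windows, scaling)
  if (any(windows$i680 <= 0) || any(windows$i850 <= 0)) {
    stop("domain error: scaled intensities must be positive", call. = FALSE)
  }
  ln680 <- log(windows$i680)
  ln850 <- log(windows$i850)
  if (any(abs(ln850) <= eps_denominator)) {
    stop("degenerate-denominator: |ln(i850)| below epsilon (scaled i850 ~ 1)",
         call. = FALSE)
  }
  ratio <- ln680 / ln850
  meta_cols <- intersect(c("sample_id", "sensor_id", "day_id"), names(windows))
  out <- cbind(windows[, meta_cols, drop = FALSE],
               data.frame(ln680 = ln680, ln850 = ln850, ratio = ratio,
                          ln680_sq = ln680^2, ln850_sq = ln850^2,
                          ratio_sq = ratio^2, ln680_ln850 = ln680 * ln850,
                          ln680_ratio = ln680 * ratio,
                          intercept = rep(1, length(ln680))))
  rownames(out) <- NULL
  out
}

#' Extract the nine-column term matrix from a feature table
#'
#' @param features Data frame from [build_features()].
#' @return Numeric matrix with columns in the canonical term order.
#' @export
feature_terms <- function(features) {
  stop_missing_cols(features, feature_term_names, "features")
  as.matrix(features[, feature_term_names, drop = FALSE])
}
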