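# CSV dialect used throughout: comma-separated, header row, UTF-8,
# '.' decimal separator, no thousands separators.

stop_missing_cols <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("format error in %s: missing column(s) %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

read_csv_plain <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  as.data.frame(data.table::fread(path, sep = ",", header = TRUE,
                                  na.strings = "NA", data.table = FALSE))
}

#' Read a raw intensity stream CSV
#'
#' One row per 20 Hz analog front-end reading. Required columns:
#' `timestamp_s,sensor_id,wavelength_nm,adc_counts,pulse_number`.
#'
#' @param path Path to a CSV file.
#' @return A data frame with the columns above.
#' @export
read_intensity_csv <- function(path) {
  df <- read_csv_plain(path)
  stop_missing_cols(df, c("timestamp_s", "sensor_id", "wavelength_nm",
                          "adc_counts", "pulse_number"), path)
  df
}

#' Read an intensity-window CSV
#'
#' One row per (blood sample, sensor) window summary. Required columns:
#' `sample_id,sensor_id,day_id,i680,i850,n_points`.
#'
#' @param path Path to a CSV file.
#' @return A data frame with the columns above.
#' @export
read_windows_csv <- function(path) {
  df <- read_csv_plain(path)
  stop_missing_cols(df, c("sample_id", "sensor_id", "day_id",
                          "i680", "i850", "n_points"), path)
  df
}

#' Read a blood-gas reference CSV
#'
#' One row per blood-gas analyzer draw. Required columns:
#' `sample_id,day_id,timestamp_s,hgb_gdl,so2_pct`.
#'
#' @param path Path to a CSV file.
#' @return A data frame with the columns above.
#' @export
read_bloodgas_csv <- function(path) {
  df <- read_csv_plain(path)
  stop_missing_cols(df, c("sample_id", "day_id", "timestamp_s",
                          "hgb_gdl", "so2_pct"), path)
  df
}

read_predictions_csv <- function(path) {
  df <- read_csv_plain(path)
  stop_missing_cols(df, c("sample_id", "sensor_id", "hgb_pred_gdl",
                          "so2_pred_pct", "so2_clamped"), path)
  df
}

write_csv_plain <- function(df, path) {
  data.table::fwrite(df, path, sep = ",", quote = FALSE, na = "NA")
  invisible(path)
}

# Sidecar JSON recording how an output file was produced (seed + config),
# so any run can be reproduced from its snapshot alone.
write_config_snapshot <- function(config, path) {
  config$schema_version <- "1.0"
  config$package_version <- as.character(utils::packageVersion("oximcal"))
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
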