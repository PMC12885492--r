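check_pairs <- function(predicted, reference, min_n = 1L) {
  if (length(predicted) != length(reference)) {
    stop("predicted and reference must have equal length", call. = FALSE)
  }
  if (length(predicted) < min_n) {
    stop(if (min_n <= 1L) "empty-input: no paired measurements"
         else "insufficient-data: need at least 2 paired measurements",
         call. = FALSE)
  }
  invisible(NULL)
}

#' Mean absolute difference between sensor and reference
#'
#' `MAD = sum |s_i - b_i| / n` where `s_i` is the sensor prediction and
#' `b_i` the paired blood-gas reference value. Named `mad_error` to avoid
#' masking the median absolute deviation [stats::mad()].
#'
#' @param predicted,reference Equal-length numeric vectors, same units.
#' @return Scalar MAD in the input units.
#' @export
mad_error <- function(predicted, reference) {
  check_pairs(predicted, reference, 1L)
  mean(abs(predicted - reference))
}

#' Accuracy root-mean-square error
#'
#' `ARMS = sqrt( sum (s_i - b_i)^2 / n )`, the standard pulse-oximetry
#' accuracy metric against an invasive reference.
#'
#' @inheritParams mad_error
#' @return Scalar ARMS in the input units.
#' @export
arms <- function(predicted, reference) {
  check_pairs(predicted, reference, 1L)
  sqrt(mean((predicted - reference)^2))
}

#' Bland-Altman bias and limits of agreement
#'
#' Bias is the mean of the paired differences (predicted minus reference);
#' the limits of agreement are `bias +- 1.96 * sd` of the differences
#' (sample standard deviation, n-1 denominator). The 1.96 multiplier is
#' used without a small-sample correction, as in standard method-comparison
#' practice.
#'
#' @inheritParams mad_error
#' @return List with `bias`, `loa_low`, `loa_high`, `sd_diff`, `n`.
#' @export
bland_altman <- function(predicted, reference) {
  check_pairs(predicted, reference, 2L)
  d <- predicted - reference
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd_diff = s, n = length(d))
}

#' Coefficient of determination against the identity line, with adjustment
#'
#' By default R-squared is computed against the identity line:
#' `R2 = 1 - sum (s - b)^2 / sum (b - mean(b))^2`, i.e. residuals are taken
#' about the reference values themselves, making R-squared a pure accuracy
#' measure (it can be negative for a poor predictor). The alternative
#' squared Pearson correlation, which ignores bias and scale errors, is
#' available via `method = "pearson"`. The adjusted value is
#' `1 - (1 - R2) (n - 1) / (n - p - 1)` with `p = n_predictors`.
#'
#' @inheritParams mad_error
#' @param n_predictors Number of model predictors `p` for the adjustment
#'   (8 for the hemoglobin library's non-constant terms, 4 for the
#'   saturation model's coefficients).
#' @param method `"identity"` (default) or `"pearson"`.
#' @return List with `r2` and `adj_r2`.
#' @export
r_squared <- function(predicted, reference, n_predictors,
                      method = c("identity", "pearson")) {
  method <- match.arg(method)
  check_pairs(predicted, reference, 2L)
  n <- length(predicted)
  if (var(reference) == 0) {
    stop("undefined-r2: reference values have zero variance", call. = FALSE)
  }
  r2 <- if (method == "identity") {
    1 - sum((predicted - reference)^2) /
      sum((reference - mean(reference))^2)
  } else {
    stats::cor(predicted, reference)^2
  }
  adj <- 1 - (1 - r2) * (n - 1) / (n - n_predictors - 1)
  list(r2 = r2, adj_r2 = adj)
}

#' Per-day mean absolute difference
#'
#' [mad_error()] applied within each experiment day; the global MAD is the
#' n-weighted mean of the per-day values.
#'
#' @inheritParams mad_error
#' @param day_id Day identifier per pair.
#' @return Named numeric vector, one MAD per day.
#' @export
per_day_mad <- function(predicted, reference, day_id) {
  check_pairs(predicted, reference, 1L)
  if (length(day_id) != length(predicted)) {
    stop("day_id must match the paired measurements in length", call. = FALSE)
  }
  vapply(split(seq_along(predicted), day_id),
         function(ix) mad_error(predicted[ix], reference[ix]), numeric(1))
}

#' Full agreement report for one (sensor, split, parameter) set of pairs
#'
#' Bundles ARMS, MAD, identity-line R-squared and adjusted R-squared,
#' Bland-Altman bias and limits of agreement, and (when day identifiers are
#' supplied) per-day MADs.
#'
#' @inheritParams r_squared
#' @param day_id Optional day identifiers for per-day MADs.
#' @param sensor_id,split,parameter Labels carried into the report.
#' @return An object of class `agreement_report` (a list); see
#'   [as.data.frame.agreement_report()] for the tidy one-row form.
#' @export
agreement_report <- function(predicted, reference, n_predictors,
                             day_id = NULL, sensor_id = NA, split = NA,
                             parameter = NA,
                             method = c("identity", "pearson")) {
  check_pairs(predicted, reference, 2L)
  ba <- bland_altman(predicted, reference)
  r2 <- r_squared(predicted, reference, n_predictors, method)
  structure(list(sensor_id = sensor_id, split = split, parameter = parameter,
                 n = length(predicted),
                 arms = arms(predicted, reference),
                 mad = mad_error(predicted, reference),
                 r2 = r2$r2, adj_r2 = r2$adj_r2,
                 bias = ba$bias, loa_low = ba$loa_low,
                 loa_high = ba$loa_high, sd_diff = ba$sd_diff,
                 per_day_mad = if (!is.null(day_id)) {
                   per_day_mad(predicted, reference, day_id)
                 }),
            class = "agreement_report")
}

#' Tidy one-row form of an agreement report
#'
#' @param x An `agreement_report`.
#' @param ... Unused.
#' @return One-row data frame with columns
#'   `sensor_id,split,parameter,n,arms,mad,r2,adj_r2,bias,loa_low,loa_high`.
#' @export
as.data.frame.agreement_report <- function(x, ...) {
  data.frame(sensor_id = x$sensor_id, split = x$split,
             parameter = x$parameter, n = x$n, arms = x$arms, mad = x$mad,
             r2 = x$r2, adj_r2 = x$adj_r2, bias = x$bias,
             loa_low = x$loa_low, loa_high = x$loa_high)
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement report (sensor %s, %s, %s): n = %d\n",
              x$sensor_id, x$split, x$parameter, x$n))
  cat(sprintf("  ARMS %.4g | MAD %.4g | R2 %.4f | adj R2 %.4f\n",
              x$arms, x$mad, x$r2, x$adj_r2))
  cat(sprintf("  Bland-Altman bias %.4g, LOA [%.4g, %.4g]\n",
              x$bias, x$loa_low, x$loa_high))
  invisible(x)
}
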