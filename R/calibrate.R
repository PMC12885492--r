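#' Split samples into calibration and validation sets, stratified by day
#'
#' Samples are split day by day so that both sets contain every experiment
#' day: within each day, a seeded random subset of approximately
#' `fraction` of the day's samples goes to calibration and the rest to
#' validation, with at least one sample of each day in each set. The split
#' is disjoint, exhaustive, and deterministic given the seed.
#'
#' @param samples Data frame with columns `sample_id` and `day_id`.
#' @param fraction Calibration fraction in (0, 1); default 0.5.
#' @param seed Integer seed (split sub-stream derived from it).
#' @return List with `calibration` and `validation` vectors of sample ids.
#' @export
split_calibration_validation <- function(samples, fraction = 0.5, seed = 1L) {
  stop_missing_cols(samples, c("sample_id", "day_id"), "samples")
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop("parameter error: fraction must be in (0, 1)", call. = FALSE)
  }
  counts <- table(samples$day_id)
  if (any(counts < 2L)) {
    stop("each day must contribute at least 2 samples to be split",
         call. = FALSE)
  }
  set.seed(derive_seed(seed, "split"))
  cal <- c()
  for (d in sort(unique(samples$day_id))) {
    ids <- samples$sample_id[samples$day_id == d]
    n_cal <- max(1L, min(length(ids) - 1L, round(fraction * length(ids))))
    cal <- c(cal, sample(ids, n_cal))
  }
  list(calibration = sort(cal),
       validation = sort(setdiff(samples$sample_id, cal)))
}

# Elastic-net objective: (1/2n) sum (y - Xw - a9)^2 +
#   lambda * [ mix * sum|w| + (1 - mix)/2 * sum w^2 ]
# over standardized non-constant features, intercept unpenalized.
# Shared 50-point logarithmic lambda ladder from the data-driven maximum at
# the smallest mixing value (so the ladder covers every mixing candidate)
# down six decades; small terminal penalties matter because calibration data
# can be nearly noise-free.
default_lambda_grid <- function(Xs, y, mixing_grid, n_lambda = 50L,
                                min_ratio = 1e-6) {
  lam_max <- max(abs(crossprod(Xs, y - mean(y)))) /
    (nrow(Xs) * max(min(mixing_grid), 1e-3))
  exp(seq(log(lam_max), log(lam_max * min_ratio), length.out = n_lambda))
}

# Exact least squares (QR) used for the unpenalized candidate; errors on
# rank deficiency instead of silently dropping columns.
ols_fit <- function(Xs, y) {
  qrx <- qr(cbind(1, Xs))
  if (qrx$rank < ncol(Xs) + 1L) {
    stop("rank-deficiency: design is singular at lambda = 0", call. = FALSE)
  }
  qr.coef(qrx, y)
}

#' Fit the sparse polynomial hemoglobin model
#'
#' Fits `Hgb = a1*ln680^2 + a2*ln850^2 + a3*R^2 + a4*ln680 + a5*ln850 +
#' a6*R + a7*ln680*ln850 + a8*ln680*R + a9` by elastic-net regression over
#' the standardized non-constant terms, selecting the penalty weight and
#' mixing fraction by k-fold cross-validation (default 5 folds, seeded fold
#' assignment). The penalized path is computed with glmnet; the `lambda = 0`
#' candidate is solved exactly by QR least squares, so at zero penalty the
#' fit coincides with ordinary least squares. Reported coefficients are
#' de-standardized back to the raw feature scale, the intercept `a9`
#' absorbing the centering shift.
#'
#' @param features Feature table from [build_features()] (or a matrix whose
#'   columns follow the canonical term order).
#' @param truth_hgb Blood-gas hemoglobin, g/dL. Values outside 2-20 g/dL
#'   trigger a warning.
#' @param cv_folds Number of cross-validation folds (>= 2, default 5).
#' @param mixing_grid Candidate elastic-net mixing fractions in `[0, 1]`
#'   (1 = pure lasso); default `c(0.1, 0.5, 0.9)`.
#' @param lambda_grid Optional penalty ladder; may include 0. Default: a
#'   50-point logarithmic ladder from the data-driven maximum.
#' @param seed Integer seed for the fold-assignment sub-stream.
#' @return An object of class `hgb_model` with elements `coeffs` (named
#'   a1..a9, raw scale), `penalty_lambda`, `mixing`, `cv_folds`,
#'   `feature_means`, `feature_scales`, and the CV error table `cv_table`.
#' @export
fit_hgb_model <- function(features, truth_hgb, cv_folds = 5L,
                          mixing_grid = c(0.1, 0.5, 0.9),
                          lambda_grid = NULL, seed = 1L) {
  terms <- if (is.matrix(features)) features else feature_terms(features)
  y <- as.numeric(truth_hgb)
  n <- length(y)
  if (nrow(terms) != n) stop("features and truth_hgb lengths differ",
                             call. = FALSE)
  if (cv_folds < 2L) stop("cv_folds must be >= 2", call. = FALSE)
  if (n < cv_folds) {
    stop("fold error: need at least as many samples as folds", call. = FALSE)
  }
  if (any(y < 2 | y > 20)) {
    warning(sprintf("%d reference Hgb value(s) outside 2-20 g/dL",
                    sum(y < 2 | y > 20)))
  }
  X <- terms[, seq_len(8L), drop = FALSE]
  means <- colMeans(X)
  scales <- apply(X, 2L, sd)
  if (any(scales == 0)) {
    stop("rank-deficiency: constant non-intercept feature column",
         call. = FALSE)
  }
  Xs <- sweep(sweep(X, 2L, means), 2L, scales, "/")
  if (is.null(lambda_grid)) {
    lambda_grid <- default_lambda_grid(Xs, y, mixing_grid)
  }
  lambda_grid <- sort(unique(lambda_grid), decreasing = TRUE)

  set.seed(derive_seed(seed, "cv"))
  foldid <- sample(rep(seq_len(cv_folds), length.out = n))

  pos <- lambda_grid > 0
  cv_mse <- matrix(NA_real_, length(mixing_grid), length(lambda_grid),
                   dimnames = list(mixing = mixing_grid, lambda = NULL))
  for (a in seq_along(mixing_grid)) {
    sq_err <- matrix(0, n, length(lambda_grid))
    for (f in seq_len(cv_folds)) {
      tr <- foldid != f
      pred <- matrix(NA_real_, sum(!tr), length(lambda_grid))
      if (any(pos)) {
        path <- glmnet::glmnet(Xs[tr, , drop = FALSE], y[tr],
                               alpha = mixing_grid[a],
                               lambda = lambda_grid[pos],
                               standardize = FALSE, thresh = 1e-10,
                               maxit = 1e6)
        pred[, pos] <- predict(path, Xs[!tr, , drop = FALSE],
                               s = lambda_grid[pos])
      }
      if (any(!pos)) {
        b0 <- ols_fit(Xs[tr, , drop = FALSE], y[tr])
        pred[, !pos] <- cbind(1, Xs[!tr, , drop = FALSE]) %*% b0
      }
      sq_err[!tr, ] <- (pred - y[!tr])^2
    }
    cv_mse[a, ] <- colMeans(sq_err)
  }
  best <- which(cv_mse == min(cv_mse), arr.ind = TRUE)[1L, ]
  mixing <- mixing_grid[best[[1L]]]
  lambda <- lambda_grid[best[[2L]]]

  if (lambda == 0) {
    b <- ols_fit(Xs, y)
    b_std <- b[-1L]; a9_std <- b[1L]
  } else {
    fit <- glmnet::glmnet(Xs, y, alpha = mixing, lambda = lambda_grid[pos],
                          standardize = FALSE, thresh = 1e-10, maxit = 1e6)
    b_all <- as.numeric(coef(fit, s = lambda))
    a9_std <- b_all[1L]; b_std <- b_all[-1L]
  }
  b_raw <- b_std / scales
  a9 <- a9_std - sum(b_raw * means)
  coeffs <- setNames(c(b_raw, a9), paste0("a", 1:9))
  structure(list(coeffs = coeffs, penalty_lambda = lambda, mixing = mixing,
                 cv_folds = as.integer(cv_folds), feature_means = means,
                 feature_scales = scales, lambda_grid = lambda_grid,
                 mixing_grid = mixing_grid, cv_table = cv_mse,
                 cv_min_mse = min(cv_mse), seed = as.integer(seed)),
            class = "hgb_model")
}

#' @export
print.hgb_model <- function(x, ...) {
  cat("Sparse polynomial hemoglobin model (9-term log-intensity library)\n")
  cat(sprintf("  selected lambda = %.4g, mixing = %.2f, %d-fold CV (MSE %.4g)\n",
              x$penalty_lambda, x$mixing, x$cv_folds, x$cv_min_mse))
  cat("  coefficients (raw scale):\n")
  print(round(x$coeffs, 6))
  invisible(x)
}

#' Predict hemoglobin concentration from the feature library
#'
#' Dot product of the raw-scale coefficients with the nine feature terms.
#' Predictions are not clamped; estimates outside the 2-20 g/dL
#' physiological range trigger a warning rather than being hidden.
#'
#' @param features Feature table from [build_features()] or a term matrix.
#' @param model A fitted [fit_hgb_model()] object.
#' @return Numeric vector of hemoglobin estimates, g/dL.
#' @export
predict_hgb <- function(features, model) {
  if (!inherits(model, "hgb_model") || is.null(model$coeffs)) {
    stop("state error: model is not a fitted hgb_model", call. = FALSE)
  }
  terms <- if (is.matrix(features)) features else feature_terms(features)
  pred <- drop(terms %*% model$coeffs)
  n_out <- sum(pred < 2 | pred > 20)
  if (n_out > 0L) {
    warning(sprintf("%d Hgb prediction(s) outside 2-20 g/dL", n_out))
  }
  pred
}

# Bin assignment: nearest integer g/dL center, ties at the midpoint going
# to the lower center; samples farther than halfwidth from every center
# (possible when halfwidth < 0.5) are left unassigned.
hgb_bin_center <- function(hgb, halfwidth) {
  center <- ceiling(hgb - 0.5)
  center[abs(hgb - center) > halfwidth] <- NA_integer_
  center
}

#' Fit the concentration-corrected ratiometric saturation model
#'
#' Two-stage fit of `SO2 = alpha * R + beta` with `alpha = m_alpha * Hgb +
#' b_alpha` and `beta = m_beta * Hgb + b_beta`. Stage 1 groups calibration
#' samples into hemoglobin bins (integer g/dL centers, `+- bin_halfwidth`)
#' and fits ordinary least squares of saturation on the ratio within each
#' retained bin; stage 2 fits unweighted ordinary least squares of the bin
#' slopes and intercepts on the bin centers. Binning uses blood-gas
#' (ground-truth) hemoglobin at calibration time; at inference the
#' correction is driven by the predicted hemoglobin.
#'
#' @param features Feature table from [build_features()] (the `ratio`
#'   column is used), or a numeric ratio vector.
#' @param truth_so2 Blood-gas saturation, %.
#' @param hgb_for_binning Blood-gas hemoglobin used to assign bins, g/dL.
#' @param bin_halfwidth Bin halfwidth in g/dL (default 0.5).
#' @param min_bin_size Minimum samples for a bin to be retained (default 3).
#' @return An object of class `so2_model` with `m_alpha`, `b_alpha`,
#'   `m_beta`, `b_beta`, the per-bin table `bin_fits`
#'   (`hgb_center,alpha,beta,r2,n`), and stage-2 fit R-squared values.
#' @export
fit_so2_model <- function(features, truth_so2, hgb_for_binning,
                          bin_halfwidth = 0.5, min_bin_size = 3L) {
  if (bin_halfwidth <= 0) stop("bin_halfwidth must be positive", call. = FALSE)
  R <- if (is.numeric(features)) features else features$ratio
  so2 <- as.numeric(truth_so2)
  hgb <- as.numeric(hgb_for_binning)
  if (length(R) != length(so2) || length(R) != length(hgb)) {
    stop("features, truth_so2 and hgb_for_binning lengths differ",
         call. = FALSE)
  }
  center <- hgb_bin_center(hgb, bin_halfwidth)
  fits <- list()
  for (ctr in sort(unique(center[!is.na(center)]))) {
    sel <- !is.na(center) & center == ctr
    if (sum(sel) < min_bin_size) next
    if (sd(R[sel]) == 0 || sd(so2[sel]) == 0) next
    fit <- lm(so2[sel] ~ R[sel])
    r2 <- 1 - sum(stats::residuals(fit)^2) /
      sum((so2[sel] - mean(so2[sel]))^2)
    fits[[length(fits) + 1L]] <- data.frame(
      hgb_center = ctr, alpha = unname(coef(fit)[2L]),
      beta = unname(coef(fit)[1L]), r2 = r2, n = sum(sel))
  }
  if (length(fits) < 2L) {
    stop("insufficient-structure: need at least 2 usable hemoglobin bins",
         call. = FALSE)
  }
  bin_fits <- do.call(rbind, fits)
  fa <- lm(alpha ~ hgb_center, data = bin_fits)
  fb <- lm(beta ~ hgb_center, data = bin_fits)
  r2_of <- function(fit, yv) 1 - sum(stats::residuals(fit)^2) /
    sum((yv - mean(yv))^2)
  structure(list(m_alpha = unname(coef(fa)[2L]), b_alpha = unname(coef(fa)[1L]),
                 m_beta = unname(coef(fb)[2L]), b_beta = unname(coef(fb)[1L]),
                 bin_halfwidth = bin_halfwidth,
                 min_bin_size = as.integer(min_bin_size),
                 bin_fits = bin_fits,
                 alpha_fit_r2 = r2_of(fa, bin_fits$alpha),
                 beta_fit_r2 = r2_of(fb, bin_fits$beta)),
            class = "so2_model")
}

#' @export
print.so2_model <- function(x, ...) {
  cat("Concentration-corrected ratiometric SO2 model\n")
  cat(sprintf("  alpha = %.4g * Hgb + %.4g   (stage-2 R^2 = %.3f)\n",
              x$m_alpha, x$b_alpha, x$alpha_fit_r2))
  cat(sprintf("  beta  = %.4g * Hgb + %.4g   (stage-2 R^2 = %.3f)\n",
              x$m_beta, x$b_beta, x$beta_fit_r2))
  cat(sprintf("  %d bins retained (halfwidth %.2f g/dL), bin R^2 range %.3f-%.3f\n",
              nrow(x$bin_fits), x$bin_halfwidth, min(x$bin_fits$r2),
              max(x$bin_fits$r2)))
  invisible(x)
}

#' Predict oxygen saturation from the ratio and a hemoglobin estimate
#'
#' Applies `SO2 = (m_alpha * Hgb + b_alpha) * R + (m_beta * Hgb + b_beta)`,
#' clamped to the physical range `[0, 100]`. In deployment the hemoglobin
#' estimate comes from [predict_hgb()], not from the reference instrument.
#'
#' @param features Feature table (its `ratio` column) or a ratio vector.
#' @param hgb_estimate Hemoglobin estimate(s), g/dL.
#' @param model A fitted [fit_so2_model()] object.
#' @return Numeric vector of saturations in %, with a logical attribute
#'   `"clamped"` marking entries that hit the `[0, 100]` bounds.
#' @export
predict_so2 <- function(features, hgb_estimate, model) {
  if (!inherits(model, "so2_model") || is.null(model$m_alpha)) {
    stop("state error: model is not a fitted so2_model", call. = FALSE)
  }
  R <- if (is.numeric(features)) features else features$ratio
  alpha <- model$m_alpha * hgb_estimate + model$b_alpha
  beta <- model$m_beta * hgb_estimate + model$b_beta
  raw <- alpha * R + beta
  out <- pmin(pmax(raw, 0), 100)
  attr(out, "clamped") <- raw < 0 | raw > 100
  out
}
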