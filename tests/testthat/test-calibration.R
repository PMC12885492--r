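test_that("the day-stratified split is disjoint, exhaustive and deterministic", {
  bg <- default_run()$sim$bloodgas
  sp <- split_calibration_validation(bg, fraction = 0.5, seed = 7L)
  expect_length(intersect(sp$calibration, sp$validation), 0)
  expect_setequal(c(sp$calibration, sp$validation), bg$sample_id)
  days_cal <- unique(bg$day_id[bg$sample_id %in% sp$calibration])
  days_val <- unique(bg$day_id[bg$sample_id %in% sp$validation])
  expect_setequal(days_cal, unique(bg$day_id))
  expect_setequal(days_val, unique(bg$day_id))
  expect_identical(sp, split_calibration_validation(bg, 0.5, seed = 7L))
  expect_false(identical(sp, split_calibration_validation(bg, 0.5, seed = 8L)))

  tiny <- data.frame(sample_id = 1:4, day_id = c(1, 1, 2, 2))
  sp2 <- split_calibration_validation(tiny, 0.5, seed = 1L)
  expect_length(sp2$calibration, 2)
  expect_setequal(tiny$day_id[tiny$sample_id %in% sp2$calibration], c(1, 2))
  expect_error(split_calibration_validation(tiny, 1.2, 1L), "parameter")
  expect_error(split_calibration_validation(tiny, 0, 1L), "parameter")
})

test_that("the unpenalized elastic-net fit matches normal-equations least squares", {
  for (i in 1:20) {
    f <- random_features(n = sample(20:50, 1), seed = 100 + i)
    terms <- feature_terms(f)
    set.seed(200 + i)
    y <- drop(terms %*% c(0.1, -0.2, 0.3, 1, -1.5, 2, 0.05, -0.1, 5)) +
      rnorm(nrow(terms), 0, 0.3)
    model <- fit_hgb_model(f, y, lambda_grid = 0, seed = 1L,
                           mixing_grid = 0.5) |> suppressWarnings()
    # independent oracle: solve the normal equations directly
    X <- cbind(terms[, 1:8], 1)
    beta <- unname(drop(solve(crossprod(X), crossprod(X, y))))
    expect_equal(unname(model$coeffs), beta, tolerance = 1e-8)
  }
})

test_that("a pure ratio-plus-intercept target is recovered exactly", {
  f <- random_features(60, seed = 42)
  y <- 2 * f$ratio + 5
  model <- suppressWarnings(fit_hgb_model(
    f, y, lambda_grid = c(10^seq(0, -6, length.out = 20), 0), seed = 3L))
  expect_equal(unname(model$coeffs["a6"]), 2, tolerance = 1e-6)
  expect_equal(unname(model$coeffs["a9"]), 5, tolerance = 1e-6)
  expect_equal(max(abs(model$coeffs[c(1:5, 7:8)])), 0, tolerance = 1e-6)
})

test_that("an overwhelming penalty shrinks to the intercept-only model", {
  f <- random_features(40, seed = 9)
  y <- 10 + f$ratio + rnorm(40, 0, 0.1)
  model <- suppressWarnings(fit_hgb_model(f, y, lambda_grid = 1e6, seed = 1L))
  expect_equal(unname(model$coeffs[1:8]), rep(0, 8))
  expect_equal(unname(model$coeffs["a9"]), mean(y))
})

test_that("fitting is reproducible under a fixed seed", {
  run <- default_run()
  feats <- build_features(run$sim$windows, run$scaling)
  cal <- feats$sample_id %in% run$split$calibration
  bg <- run$sim$bloodgas[match(feats$sample_id[cal],
                               run$sim$bloodgas$sample_id), ]
  m1 <- fit_hgb_model(feats[cal, ], bg$hgb_gdl, seed = 4L)
  m2 <- fit_hgb_model(feats[cal, ], bg$hgb_gdl, seed = 4L)
  expect_identical(m1$penalty_lambda, m2$penalty_lambda)
  expect_identical(m1$mixing, m2$mixing)
  expect_identical(m1$coeffs, m2$coeffs)
})

test_that("the L1 norm of the selected coefficients shrinks as the penalty grows", {
  run <- default_run()
  feats <- build_features(run$sim$windows, run$scaling)
  cal <- feats$sample_id %in% run$split$calibration
  bg <- run$sim$bloodgas[match(feats$sample_id[cal],
                               run$sim$bloodgas$sample_id), ]
  ladder <- 10^seq(-4, 1, length.out = 8)
  l1 <- vapply(ladder, function(lam) {
    m <- fit_hgb_model(feats[cal, ], bg$hgb_gdl, lambda_grid = lam,
                       mixing_grid = 0.5, seed = 1L)
    sum(abs(m$coeffs[1:8] * m$feature_scales))
  }, numeric(1))
  expect_true(all(diff(l1) <= 1e-8))
})

test_that("hemoglobin prediction is the dot product with the feature terms", {
  f <- build_features(make_windows(exp(2), exp(1), 1L))
  expect_equal(predict_hgb(f, manual_hgb_model(c(rep(0, 8), 12))), 12)
  expect_equal(suppressWarnings(
    predict_hgb(f, manual_hgb_model(c(rep(0, 5), 1, 0, 0, 0)))), 2)
  # direct summation of [4,1,4,2,1,2,2,4,1] with unit coefficients
  expect_equal(suppressWarnings(predict_hgb(f, manual_hgb_model(rep(1, 9)))),
               21)
  expect_error(predict_hgb(f, structure(list(), class = "hgb_model")),
               "state error")
  expect_warning(predict_hgb(f, manual_hgb_model(c(rep(0, 8), 30))),
                 "outside 2-20")
})

test_that("the two-stage saturation fit recovers an exact linear structure", {
  set.seed(31)
  hgb <- rep(6:14, each = 8)
  R <- runif(length(hgb), 0.5, 1.5)
  so2 <- (2 * hgb) * R + (3 * hgb + 1)
  model <- fit_so2_model(R, so2, hgb)
  expect_equal(model$m_alpha, 2, tolerance = 1e-9)
  expect_equal(model$b_alpha, 0, tolerance = 1e-9)
  expect_equal(model$m_beta, 3, tolerance = 1e-9)
  expect_equal(model$b_beta, 1, tolerance = 1e-9)
  expect_true(all(model$bin_fits$r2 > 1 - 1e-12))
  expect_equal(nrow(model$bin_fits), 9)

  expect_error(fit_so2_model(R[hgb == 6], so2[hgb == 6], hgb[hgb == 6]),
               "insufficient-structure")
})

test_that("saturation bins are centered on integers with ties to the lower center", {
  set.seed(5)
  hgb <- c(6.5, 6.49, 6.51, rep(c(6, 7), each = 5))
  R <- runif(length(hgb)); so2 <- 50 + 30 * R + hgb
  model <- fit_so2_model(R, so2, hgb)
  # 6.5 ties down to 6; 6.49 joins 6; 6.51 joins 7
  expect_equal(model$bin_fits$n, c(7, 6))
})

test_that("every retained bin of the noiseless calibration is near-perfectly linear", {
  model <- noiseless_run()$bundle$so2_model
  expect_gte(nrow(model$bin_fits), 2)
  expect_true(all(model$bin_fits$r2 >= 0.99))
})

test_that("saturation prediction applies the concentration correction and clamps", {
  m <- manual_so2_model(0, 100, 0, 0)
  expect_equal(as.numeric(predict_so2(0.5, 10, m)), 50)
  expect_false(attr(predict_so2(0.5, 10, m), "clamped"))

  hot <- manual_so2_model(0, 0, 0, 120)
  p <- predict_so2(0.5, 10, hot)
  expect_equal(as.numeric(p), 100)
  expect_true(attr(p, "clamped"))

  m2 <- manual_so2_model(2, 0, 3, 1)
  expect_equal(as.numeric(predict_so2(2, 10, m2)), 71)
  expect_error(predict_so2(0.5, 10, structure(list(), class = "so2_model")),
               "state error")
})

test_that("one calibration bundle serves both sensors with comparable accuracy", {
  rep <- default_run()$reports
  val <- rep[rep$split == "validation", ]
  for (param in c("hgb", "so2")) {
    a <- val$arms[val$parameter == param]
    expect_length(a, 2)
    expect_lt(abs(diff(a)) / mean(a), 0.25)
  }
})

test_that("calibration bundles round-trip through JSON losslessly", {
  run <- default_run()
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration_bundle(run$bundle, path)
  back <- read_calibration_bundle(path)
  expect_equal(back$hgb_model$coeffs, run$bundle$hgb_model$coeffs)
  expect_equal(back$hgb_model$penalty_lambda,
               run$bundle$hgb_model$penalty_lambda)
  expect_equal(back$so2_model$m_alpha, run$bundle$so2_model$m_alpha)
  expect_equal(back$so2_model$bin_fits, run$bundle$so2_model$bin_fits)
  expect_equal(back$scalings, run$bundle$scalings)
  expect_equal(back$provenance$seed, run$bundle$provenance$seed)
})
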