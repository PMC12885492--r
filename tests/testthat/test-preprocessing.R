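test_that("pulse-number normalization divides counts by pulses and rejects bad records", {
  expect_equal(normalize_by_pulse_count(65535, 127), 65535 / 127)
  expect_equal(normalize_by_pulse_count(0, 50), 0)
  expect_equal(normalize_by_pulse_count(1000, 1), 1000)
  expect_equal(normalize_by_pulse_count(c(100, 200), c(10, 20)), c(10, 10))
  expect_error(normalize_by_pulse_count(100, 0), "invalid-record")
  expect_error(normalize_by_pulse_count(-5, 10), "invalid-record")
  expect_error(normalize_by_pulse_count(70000, 10), "invalid-record")
})

test_that("window averaging takes per-wavelength means and flags incomplete windows", {
  recs <- raw_records(i680 = c(4, 6), i850 = 3)
  w <- window_average(recs, sample_id = 7L, day_id = 2L)
  expect_equal(w$i680, 5)
  expect_equal(w$i850, 3)
  expect_equal(w$n_points, 1L)
  expect_equal(w$sample_id, 7L)

  single <- window_average(raw_records(i680 = 4.5, i850 = 2.5))
  expect_equal(single$i680, 4.5)
  expect_equal(single$i850, 2.5)

  only680 <- raw_records(i680 = c(4, 6), i850 = numeric(0))
  expect_error(window_average(only680), "incomplete-window")

  two_sensors <- rbind(raw_records(4, 3, sensor_id = 1L),
                       raw_records(5, 2, sensor_id = 2L))
  expect_error(window_average(two_sensors), "single sensor")
})

test_that("cross-sensor scaling maps every sensor to the grand mean", {
  w <- rbind(make_windows(2.0, 1.0, sensor_id = 1L),
             make_windows(4.0, 1.0, sensor_id = 2L, sample_id = 2L))
  sc <- compute_sensor_scaling(w)
  expect_equal(sc$scale680, c(1.5, 0.75))

  one <- make_windows(c(2, 2.4), c(1, 1.2), sensor_id = 1L)
  expect_equal(compute_sensor_scaling(one)$scale680, 1)
  expect_equal(compute_sensor_scaling(one)$scale850, 1)

  three <- rbind(make_windows(1, 1, 1L), make_windows(2, 2, 2L),
                 make_windows(3, 3, 3L))
  expect_equal(compute_sensor_scaling(three)$scale680, c(2, 1, 2 / 3))

  expect_error(compute_sensor_scaling(three, sensor_ids = 1:4),
               "missing-sensor")
})

test_that("scaling is idempotent and equalizes per-wavelength scaled means", {
  set.seed(11)
  w <- rbind(
    make_windows(exp(rnorm(20, 2, 0.3)), exp(rnorm(20, 1, 0.2)), 1L),
    make_windows(1.7 * exp(rnorm(20, 2, 0.3)), 0.6 * exp(rnorm(20, 1, 0.2)),
                 2L, sample_id = 21:40))
  sc <- compute_sensor_scaling(w)
  scaled <- apply_sensor_scaling(w, sc)
  m680 <- tapply(scaled$i680, scaled$sensor_id, mean)
  m850 <- tapply(scaled$i850, scaled$sensor_id, mean)
  expect_lt(abs(diff(m680)) / mean(m680), 1e-9)
  expect_lt(abs(diff(m850)) / mean(m850), 1e-9)

  sc2 <- compute_sensor_scaling(scaled)
  expect_equal(sc2$scale680, c(1, 1), tolerance = 1e-12)
  expect_equal(sc2$scale850, c(1, 1), tolerance = 1e-12)
})

test_that("feature library follows the canonical nine-term layout", {
  w <- make_windows(exp(2), exp(1), sensor_id = 1L)
  f <- build_features(w)
  expect_equal(f$ln680, 2)
  expect_equal(f$ln850, 1)
  expect_equal(f$ratio, 2)
  expect_equal(unname(feature_terms(f)[1, ]), c(4, 1, 4, 2, 1, 2, 2, 4, 1))
  # the library has an ln680*R cross term but deliberately no ln850*R term
  expect_true("ln680_ratio" %in% colnames(feature_terms(f)))
  expect_false(any(grepl("ln850_ratio", colnames(feature_terms(f)))))

  sym <- build_features(make_windows(exp(1), exp(1), 1L))
  expect_equal(sym$ratio, 1)

  expect_error(build_features(make_windows(exp(2), 1.0, 1L)),
               "degenerate-denominator")
  expect_error(build_features(make_windows(-1, exp(1), 1L)), "domain")
})

test_that("the ratio is computed from scaled intensities and is order-independent", {
  set.seed(3)
  w <- rbind(
    make_windows(exp(rnorm(10, 2, 0.2)), exp(rnorm(10, 1, 0.1)), 1L),
    make_windows(1.4 * exp(rnorm(10, 2, 0.2)), 0.8 * exp(rnorm(10, 1, 0.1)),
                 2L, sample_id = 11:20))
  sc <- compute_sensor_scaling(w)
  f1 <- build_features(w, sc)
  # scaling acts additively on log-intensities
  idx <- w$sensor_id == 2L
  expect_equal(f1$ln680[idx], log(w$i680[idx]) + log(sc$scale680[2]))
  expect_equal(f1$ratio, f1$ln680 / f1$ln850)
  # permuting window order permutes but does not change the features
  perm <- sample(nrow(w))
  f2 <- build_features(w[perm, ], sc)
  expect_equal(f2$ratio[order(f2$sample_id, f2$sensor_id)],
               f1$ratio[order(f1$sample_id, f1$sensor_id)])
})

test_that("windows reconstructed from the raw 20 Hz stream match the simulated windows", {
  prot <- experiment_protocol(hgb_levels = 6:9,
                              so2_steps = c(70, 80, 90, 100),
                              samples_total = 16L, n_days = 4L,
                              sampling_hz = 2, window_s = 10, seed = 5L)
  sim <- simulate_experiment(prot, profiles = default_sensor_profiles(0.003))
  raw <- emit_raw_intensity(sim)
  expect_named(raw, c("timestamp_s", "sensor_id", "wavelength_nm",
                      "adc_counts", "pulse_number"))
  expect_true(all(raw$adc_counts <= 65535 & raw$adc_counts >= 0))
  expect_true(all(raw$pulse_number >= 1 & raw$pulse_number <= 127))

  rebuilt <- windows_from_raw(raw, sim$bloodgas, window_s = prot$window_s)
  rebuilt <- rebuilt[order(rebuilt$sample_id, rebuilt$sensor_id), ]
  orig <- sim$windows[order(sim$windows$sample_id, sim$windows$sensor_id), ]
  expect_equal(nrow(rebuilt), nrow(orig))
  # ADC emission rescales by the profile's counts-per-transmittance factor
  # and quantizes to integer counts
  adc_scale <- sim$profiles[[1]]$adc_scale
  expect_equal(rebuilt$i680, orig$i680 * adc_scale, tolerance = 1e-3)
  expect_equal(rebuilt$i850, orig$i850 * adc_scale, tolerance = 1e-3)
})
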