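make_seg <- function(x, fs = 100) detect_steps(x, fs)

test_that("step slices partition the span with the stated half convention", {
  seg <- structure(list(peak_indices = c(1L, 101L, 201L),
                        step_durations_s = c(1, 1), stride_durations_s = 2,
                        cadence_spm = 60, fs_hz = 100),
                   class = "step_segmentation")
  x <- seq_len(250) / 10
  sl <- step_slices(x, seg)
  expect_length(sl$slices, 2L)
  expect_equal(sl$slices[[1]], x[1:100])
  expect_equal(sl$slices[[2]], x[101:200])
  expect_equal(unlist(sl$slices), x[1:200])              # partition
  # odd slice: first half gets the middle sample
  seg$peak_indices <- c(1L, 6L, 11L)
  sl2 <- step_slices(x, seg)
  expect_length(sl2$first_half[[1]], 3L)
  expect_length(sl2$last_half[[1]], 2L)
  expect_equal(c(sl2$first_half[[1]], sl2$last_half[[1]]), sl2$slices[[1]])
})

test_that("autocorrelation regularity matches its brute-force definition", {
  fs <- 100
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 2 * t)
  reg <- autocorr_regularity(x, fs, step_lag_s = 0.5, stride_lag_s = 1.0)
  expect_gt(reg[["StpReg"]], 0.98)
  expect_gt(reg[["StrReg"]], 0.98)
  # antiphase at half period, no search window
  reg_half <- autocorr_regularity(x, fs, step_lag_s = 0.25, stride_lag_s = 1.0,
                                  search_frac = 0)
  expect_equal(reg_half[["StpReg"]], -1, tolerance = 0.01)
  # arbitrary signal: double-loop oracle over the same lag window
  set.seed(21)
  y <- rnorm(3000)
  nominal <- 0.5 * fs
  window <- max(1, floor(nominal * 0.9)):ceiling(nominal * 1.1)
  expect_equal(autocorr_regularity(y, fs, 0.5, 1.0)[["StpReg"]],
               oracle_autocorr(y, window), tolerance = 1e-12)
  expect_error(autocorr_regularity(y, fs, 20, 1), class = "gaitfall_invalid_input")
})

test_that("white noise scores low on step regularity", {
  vals <- vapply(1:20, function(s) {
    set.seed(s)
    autocorr_regularity(rnorm(6000), 100, 0.5, 1.0)[["StpReg"]]
  }, numeric(1))
  expect_lt(mean(vals), 0.2)
  expect_true(all(vals < 0.35))
})

test_that("mean trend is near zero for stationary signals and grows with drift", {
  fs <- 100
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 2 * t)
  seg <- make_seg(normalize_max(x), fs)
  expect_lt(mean_trend(x, fs, seg), 0.01)
  expect_equal(mean_trend(rep(0, length(t)), fs, seg), 0)
  drift <- x * seq(0.5, 1.5, length.out = length(t)) + 0.2 * sin(2 * pi * 0.05 * t)
  expect_gt(mean_trend(drift, fs, seg), mean_trend(x, fs, seg))
})

test_that("per-axis time features: registry size, periodic regularity, oracle mean", {
  fs <- 100
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 2 * t)
  seg <- make_seg(normalize_max(x), fs)
  tf <- time_features_axis(x, seg, fs)
  expect_length(tf, 21L)
  expect_true(all(is.finite(tf)))
  expect_gt(tf[["StpReg"]], 0.98)
  expect_gt(tf[["StrReg"]], 0.98)
  # per-step mean equals brute-force mean of slice means
  sl <- step_slices(x, seg)
  expect_equal(tf[["mean"]], mean(vapply(sl$slices, mean, numeric(1))),
               tolerance = 1e-12)
  expect_equal(tf[["energy"]], mean(vapply(sl$slices, function(s) mean(s^2),
                                           numeric(1))), tolerance = 1e-12)
})

test_that("time features are stable under appending one sample", {
  rec <- walk_subject(seed = 31, timing_jitter = 0.02, amp_jitter = 0.05,
                      noise_sd = 0.02)
  pp <- preprocess_recording(rec)
  seg <- detect_steps(pp$band_step[, "V"], 100)
  v <- pp$band_analysis[, "V"]
  tf1 <- time_features_axis(v, seg, 100)
  tf2 <- time_features_axis(c(v, v[length(v)]), seg, 100)
  rel <- abs(tf2 - tf1) / pmax(abs(tf1), 1e-6)
  expect_true(all(rel < 0.01))
})

test_that("cross-axis features match their textbook formulas", {
  set.seed(41)
  x <- rnorm(500); z <- rnorm(500)
  self <- cross_axis_features(x, x, z)
  expect_equal(self[["corr_V_ML"]], 1)
  expect_equal(self[["cov_V_ML"]], var(x))
  anti <- cross_axis_features(x, -x, z)
  expect_equal(anti[["corr_V_ML"]], -1)
  # brute-force Pearson and n-1 covariance
  r_oracle <- sum((x - mean(x)) * (z - mean(z))) /
    sqrt(sum((x - mean(x))^2) * sum((z - mean(z))^2))
  cov_oracle <- sum((x - mean(x)) * (z - mean(z))) / (length(x) - 1)
  got <- cross_axis_features(x, z, z)
  expect_equal(got[["corr_V_ML"]], r_oracle, tolerance = 1e-12)
  expect_equal(got[["cov_V_ML"]], cov_oracle, tolerance = 1e-12)
  expect_error(cross_axis_features(x, rep(1, 500), z),
               class = "gaitfall_degenerate_signal")
})

test_that("step regularity decreases with injected timing jitter", {
  jitters <- c(0, 0.04, 0.08)
  means <- vapply(jitters, function(j) {
    vals <- vapply(1:30, function(s) {
      rec <- walk_subject(seed = 100 + s, f_step = 1.9, timing_jitter = j,
                          amp_jitter = 0.05, noise_sd = 0.02, duration_s = 30)
      pp <- preprocess_recording(rec)
      seg <- detect_steps(pp$band_step[, "V"], 100)
      autocorr_regularity(pp$band_analysis[, "V"], 100,
                          mean(seg$step_durations_s),
                          mean(seg$stride_durations_s))[["StpReg"]]
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})
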