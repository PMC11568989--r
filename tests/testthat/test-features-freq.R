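flat_psd <- function(m = 30, value = 2) {
  f <- seq(0.5, 15, length.out = m)
  psd_estimate(c(0, f), c(0, rep(value, m)))
}

test_that("Tukey window has the closed-form taper shape", {
  w <- tukey_window(101, 0.5)
  expect_equal(w[1], 0)
  expect_equal(w[101], 0)
  expect_equal(w[51], 1)
  expect_true(all(w >= 0 & w <= 1))
  # flat section spans the middle 1 - alpha fraction
  expect_true(all(w[27:75] == 1))
  expect_equal(tukey_window(64, 0), rep(1, 64))
})

test_that("periodogram finds spectral lines and satisfies Parseval", {
  fs <- 100
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 2 * t)
  psd <- periodogram_tukey(x, fs)
  expect_s3_class(psd, "psd_estimate")
  expect_equal(psd$freqs_hz[which.max(psd$power)], 2, tolerance = 1 / 60 + 1e-9)
  # Parseval identity for the chosen density scaling
  w <- tukey_window(length(x), 0.5)
  df <- psd$freqs_hz[2] - psd$freqs_hz[1]
  expect_equal(sum(psd$power) * df, sum((x * w)^2) / sum(w^2), tolerance = 1e-9)
  # and approximately the mean square of a stationary signal
  expect_equal(sum(psd$power) * df, mean(x^2), tolerance = 0.05 * mean(x^2))
  expect_error(periodogram_tukey(x[1:100], fs), class = "gaitfall_invalid_input")
})

test_that("white-noise periodogram is spectrally flat on average", {
  flatness <- vapply(1:20, function(s) {
    set.seed(s)
    psd <- periodogram_tukey(rnorm(2048), 100)
    p <- psd$power[psd$band_mask]
    exp(mean(log(p))) / mean(p)
  }, numeric(1))
  expect_gt(mean(flatness), 0.5)
})

test_that("dominant peaks rank by prominence with the zero fallback", {
  fs <- 100
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 1.8 * t) + 0.4 * sin(2 * pi * 3.6 * t)
  pk <- dominant_peaks(periodogram_tukey(x, fs))
  expect_equal(pk[["F1"]], 1.8, tolerance = 1 / 60 + 1e-9)
  expect_equal(pk[["F2"]], 3.6, tolerance = 1 / 60 + 1e-9)
  expect_gt(pk[["pF1"]], pk[["pF2"]])
  expect_gt(pk[["wF1"]], 0)
  # spectrum with a single local maximum: second peak falls back to zeros
  f <- seq(0, 20, by = 0.1)
  p <- exp(-(f - 2)^2)
  single <- dominant_peaks(psd_estimate(f, p))
  expect_equal(single[["F1"]], 2, tolerance = 1e-9)
  expect_equal(unname(single[c("F2", "AmpF2", "wF2", "pF2")]), rep(0, 4))
})

test_that("peak prominences equal the exhaustive walk-down oracle", {
  set.seed(51)
  y <- abs(rnorm(200)) + 0.1
  psd <- psd_estimate(seq(0, 19.9, by = 0.1), y)
  f_in <- psd$freqs_hz[psd$band_mask]
  y_in <- psd$power[psd$band_mask]
  pk <- gaitfall:::peak_prominences(y_in)
  expect_gt(nrow(pk), 5)
  for (r in seq_len(nrow(pk)))
    expect_equal(pk$prominence[r], oracle_prominence(y_in, pk$index[r]),
                 tolerance = 1e-12)
})

test_that("flat and single-bin spectra hit their closed forms", {
  ff <- freq_features_axis(flat_psd(m = 30))
  expect_length(ff, 32L)
  expect_equal(ff[["flatness_PSD"]], 1)
  expect_equal(ff[["crest_PSD"]], 1)
  expect_equal(ff[["centroid_PSD"]], (0.5 + 15) / 2, tolerance = 1e-9)
  expect_equal(ff[["entropy_PSD"]], 1)
  # single bin carrying all power among m in-band bins
  m <- 30
  f <- seq(0.5, 15, length.out = m)
  p <- rep(0, m); p[10] <- 5
  single <- freq_features_axis(psd_estimate(c(0, f), c(0, p)))
  expect_equal(single[["crest_PSD"]], m)
  expect_equal(single[["flatness_PSD"]], 0)
  expect_equal(single[["centroid_PSD"]], f[10])
  expect_equal(single[["spread_PSD"]], 0)
  expect_error(freq_features_axis(psd_estimate(c(0, f), rep(0, m + 1))),
               class = "gaitfall_degenerate_spectrum")
})

test_that("spectral moments match brute-force weighted formulas", {
  set.seed(61)
  m <- 100
  f <- seq(0.5, 15, length.out = m)
  p <- abs(rnorm(m)) + 0.01
  ff <- freq_features_axis(psd_estimate(c(0, f), c(0, p)))
  pr <- p / sum(p)
  c0 <- sum(f * pr)
  s0 <- sqrt(sum((f - c0)^2 * pr))
  expect_equal(ff[["centroid_PSD"]], c0, tolerance = 1e-12)
  expect_equal(ff[["spread_PSD"]], s0, tolerance = 1e-12)
  expect_equal(ff[["skew_PSD"]], sum((f - c0)^3 * pr) / s0^3, tolerance = 1e-12)
  expect_equal(ff[["kurt_PSD"]], sum((f - c0)^4 * pr) / s0^4, tolerance = 1e-12)
  expect_equal(ff[["crest_PSD"]], max(p) / mean(p), tolerance = 1e-12)
  expect_equal(ff[["flatness_PSD"]], exp(mean(log(p))) / mean(p), tolerance = 1e-12)
  k <- seq_len(m)
  expect_equal(ff[["decrease_PSD"]],
               sum((p[-1] - p[1]) / (k[-1] - 1)) / sum(p[-1]), tolerance = 1e-12)
  expect_equal(ff[["slope_PSD"]], unname(coef(lm(p ~ f))[2]), tolerance = 1e-9)
  # relative band powers partition the band
  expect_equal(ff[["relpow_0p5_3"]] + ff[["relpow_3_8"]] + ff[["relpow_8_15"]],
               1, tolerance = 1e-12)
})

test_that("scale-free spectral features ignore PSD amplitude", {
  set.seed(71)
  m <- 80
  f <- seq(0.5, 15, length.out = m)
  p <- abs(rnorm(m)) + 0.05
  scale_free <- c("F1", "wF1", "F2", "wF2", "centroid_PSD", "spread_PSD",
                  "skew_PSD", "kurt_PSD", "flatness_PSD", "crest_PSD",
                  "rolloff95", "entropy_PSD", "relpow_0p5_3", "relpow_3_8",
                  "relpow_8_15", "ratio_F2F1", "medfreq")
  a <- freq_features_axis(psd_estimate(c(0, f), c(0, p)))
  b <- freq_features_axis(psd_estimate(c(0, f), c(0, 7.3 * p)))
  for (nm in scale_free)
    expect_equal(a[[nm]], b[[nm]], tolerance = 1e-9, label = nm)
})

test_that("no feature reads power outside the 0.5-15 Hz band", {
  set.seed(81)
  m <- 200
  f <- seq(0, 19.9, length.out = m)
  p <- abs(rnorm(m)) + 0.05
  p2 <- p
  out_of_band <- f < 0.5 | f > 15
  p2[out_of_band] <- p2[out_of_band] * 13
  a <- freq_features_axis(psd_estimate(f, p))
  b <- freq_features_axis(psd_estimate(f, p2))
  expect_equal(a, b, tolerance = 1e-12)
})
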