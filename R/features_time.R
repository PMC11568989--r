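#' Cut one axis's analysis-band signal into per-step slices
#'
#' Slices are half-open intervals `[p_k, p_{k+1})` between consecutive
#' detected step peaks. Each slice is also split into its first and last half
#' by sample count; an odd middle sample goes to the first half.
#'
#' @param axis_signal one axis of the 0.5–15 Hz analysis signal.
#' @param seg a [detect_steps()] segmentation.
#' @return object of class `step_slices`: list with `slices`, `first_half`,
#'   `last_half` (parallel lists of numeric vectors).
#' @export
step_slices <- function(axis_signal, seg) {
  stopifnot(inherits(seg, "step_segmentation"))
  p <- seg$peak_indices
  if (length(p) < 2L)
    gf_stop("gaitfall_no_steps", "segmentation has fewer than 2 peaks")
  if (max(p) > length(axis_signal))
    gf_stop("gaitfall_invalid_input", "signal shorter than segmentation peak indices")
  slices <- lapply(seq_len(length(p) - 1L), function(k)
    axis_signal[p[k]:(p[k + 1L] - 1L)])
  lens <- lengths(slices)
  if (any(lens < 2L))
    gf_stop("gaitfall_invalid_input", "step slice shorter than 2 samples")
  half <- ceiling(lens / 2)
  structure(
    list(slices = slices,
         first_half = Map(function(s, h) s[seq_len(h)], slices, half),
         last_half = Map(function(s, h) s[seq(h + 1L, length(s))], slices, half)),
    class = "step_slices"
  )
}

# moment-based skewness (Fisher-Pearson, population moments)
skewness_m <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(0)
  mean((x - mean(x))^3) / m2^1.5
}

# Pearson kurtosis m4/m2^2 (not excess)
kurtosis_m <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(0)
  mean((x - mean(x))^4) / m2^2
}

#' Step and stride regularity from the autocorrelation
#'
#' Unbiased autocovariance about zero, normalized by its lag-0 value,
#' evaluated at the sample lag nearest the mean step period (step
#' regularity) and the mean stride period (stride regularity). Because
#' discrete lags rarely coincide with the true period, the value reported is
#' the maximum over lags within ±10% of the nominal lag.
#'
#' Values near 1 indicate highly repeatable gait; white noise gives values
#' near 0.
#'
#' @param axis_signal numeric signal (analysis band).
#' @param fs_hz sampling rate in Hz.
#' @param step_lag_s,stride_lag_s nominal lags in seconds; each must lie in
#'   `(0, duration/4)`.
#' @param search_frac half-width of the lag search window as a fraction of
#'   the nominal lag (default 0.1).
#' @return named numeric vector `c(StpReg =, StrReg =)`.
#' @export
autocorr_regularity <- function(axis_signal, fs_hz, step_lag_s, stride_lag_s,
                                search_frac = 0.1) {
  x <- as.numeric(axis_signal)
  n <- length(x)
  dur <- n / fs_hz
  for (lag in c(step_lag_s, stride_lag_s))
    if (!(lag > 0 && lag < dur / 4))
      gf_stop("gaitfall_invalid_input", "lag %g s outside (0, %g s)", lag, dur / 4)
  c0 <- sum(x^2) / n
  if (c0 == 0) return(c(StpReg = 0, StrReg = 0))
  eval_lag <- function(lag_s) {
    nominal <- lag_s * fs_hz
    lo <- max(1L, floor(nominal * (1 - search_frac)))
    hi <- min(n - 1L, ceiling(nominal * (1 + search_frac)))
    vals <- vapply(lo:hi, function(tau)
      sum(x[seq_len(n - tau)] * x[seq(tau + 1L, n)]) / (n - tau), numeric(1))
    max(vals) / c0
  }
  c(StpReg = eval_lag(step_lag_s), StrReg = eval_lag(stride_lag_s))
}

#' Mean trend of an acceleration axis
#'
#' Moving average with a window equal to the mean step duration, then the
#' mean absolute value of that trend. A stationary zero-mean signal scores
#' near 0; slow amplitude drift or step-scale asymmetry raises the value.
#'
#' @param axis_signal numeric signal.
#' @param fs_hz sampling rate in Hz.
#' @param seg a [detect_steps()] segmentation (provides the window length).
#' @return scalar mean absolute trend.
#' @export
mean_trend <- function(axis_signal, fs_hz, seg) {
  stopifnot(inherits(seg, "step_segmentation"))
  w <- max(1L, round(mean(seg$step_durations_s) * fs_hz))
  trend <- stats::filter(as.numeric(axis_signal), rep(1 / w, w), sides = 2)
  mean(abs(trend), na.rm = TRUE)
}

#' The 21 time-domain features for one axis
#'
#' Features 1–16 are per-step statistics averaged across steps: mean, sd,
#' skewness, Pearson kurtosis, RMS, range, median, IQR, mean and sd of the
#' first and last half-step, zero-crossing rate, mean-square energy, mean
#' absolute value, mean absolute deviation. Features 17–21 are whole-signal:
#' coefficient of variation of per-step peak amplitudes, step regularity,
#' stride regularity, their ratio, and the mean trend.
#'
#' @param axis_signal one axis of the 0.5–15 Hz analysis signal.
#' @param seg a [detect_steps()] segmentation.
#' @param fs_hz sampling rate in Hz.
#' @return named numeric vector of length 21.
#' @export
time_features_axis <- function(axis_signal, seg, fs_hz) {
  sl <- step_slices(axis_signal, seg)
  per_step <- function(f, what = sl$slices) mean(vapply(what, f, numeric(1)))
  zcr <- function(s) {
    sgn <- sign(s)
    sgn <- sgn[sgn != 0]
    if (length(sgn) < 2L) return(0)
    sum(diff(sgn) != 0) / length(s)
  }
  peak_amp <- vapply(sl$slices, function(s) max(abs(s)), numeric(1))
  cv_peak <- if (mean(peak_amp) == 0) 0 else sd(peak_amp) / mean(peak_amp)
  reg <- autocorr_regularity(axis_signal, fs_hz,
                             step_lag_s = mean(seg$step_durations_s),
                             stride_lag_s = mean(seg$stride_durations_s))
  # sign-preserving clamp keeps the ratio finite when stride regularity ~ 0
  den <- if (abs(reg[["StrReg"]]) < 1e-6) sign(reg[["StrReg"]] + 1e-12) * 1e-6 else reg[["StrReg"]]
  c(mean = per_step(mean),
    std = per_step(sd),
    skew = per_step(skewness_m),
    kurt = per_step(kurtosis_m),
    rms = per_step(function(s) sqrt(mean(s^2))),
    range = per_step(function(s) diff(range(s))),
    median = per_step(median),
    iqr = per_step(function(s) unname(diff(quantile(s, c(.25, .75))))),
    mean_FH = per_step(mean, sl$first_half),
    mean_LH = per_step(mean, sl$last_half),
    std_FH = per_step(sd, sl$first_half),
    std_LH = per_step(sd, sl$last_half),
    zcr = per_step(zcr),
    energy = per_step(function(s) mean(s^2)),
    mav = per_step(function(s) mean(abs(s))),
    mad = per_step(function(s) mean(abs(s - mean(s)))),
    cv_peak_amp = cv_peak,
    StpReg = reg[["StpReg"]],
    StrReg = reg[["StrReg"]],
    reg_ratio = reg[["StpReg"]] / den,
    meanTrend = mean_trend(axis_signal, fs_hz, seg))
}

#' Cross-axis correlation and covariance features
#'
#' Pearson correlation and sample covariance (n-1 denominator) between the
#' three axis pairs of the 0.5–15 Hz analysis signals: V–ML, AP–ML, V–AP.
#'
#' @param v,ml,ap equal-length numeric vectors.
#' @return named numeric vector `corr_V_ML, corr_AP_ML, corr_V_AP, cov_V_ML,
#'   cov_AP_ML, cov_V_AP`.
#' @export
cross_axis_features <- function(v, ml, ap) {
  if (!(length(v) == length(ml) && length(ml) == length(ap)) || length(v) < 2L)
    gf_stop("gaitfall_invalid_input", "axes must have equal length >= 2")
  if (any(c(var(v), var(ml), var(ap)) == 0))
    gf_stop("gaitfall_degenerate_signal", "constant axis: correlation undefined")
  c(corr_V_ML = cor(v, ml), corr_AP_ML = cor(ap, ml), corr_V_AP = cor(v, ap),
    cov_V_ML = cov(v, ml), cov_AP_ML = cov(ap, ml), cov_V_AP = cov(v, ap))
}

# stats::sd of a length-1 vector is NA; slices are guaranteed >= 2 samples
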