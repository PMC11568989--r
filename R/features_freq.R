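#' Tukey (tapered cosine) window
#'
#' @param n window length.
#' @param alpha cosine fraction in \[0, 1\]; 0 is rectangular, 1 is Hann.
#' @return numeric vector of length `n`.
#' @export
tukey_window <- function(n, alpha = 0.5) {
  stopifnot(n >= 1, alpha >= 0, alpha <= 1)
  if (alpha == 0) return(rep(1, n))
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < alpha / 2
  hi <- t >= 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * t[hi] / alpha - 2 / alpha + 1)))
  w
}

#' Construct a PSD estimate object
#'
#' @param freqs_hz strictly increasing frequency grid from 0 to Nyquist.
#' @param power nonnegative spectral density values (unit^2 / Hz).
#' @param band analysis band in Hz (default `c(0.5, 15)`), inclusive.
#' @return object of class `psd_estimate` with a logical `band_mask`.
#' @export
psd_estimate <- function(freqs_hz, power, band = c(0.5, 15)) {
  if (any(diff(freqs_hz) <= 0))
    gf_stop("gaitfall_invalid_input", "frequency grid must be strictly increasing")
  if (any(power < 0) || any(!is.finite(power)))
    gf_stop("gaitfall_invalid_input", "power must be finite and nonnegative")
  structure(
    list(freqs_hz = freqs_hz, power = power, band = band,
         band_mask = freqs_hz >= band[1] & freqs_hz <= band[2]),
    class = "psd_estimate"
  )
}

#' Periodogram power spectral density with a Tukey taper
#'
#' Single whole-record periodogram with a Tukey window of cosine fraction
#' 0.5, one-sided density scaling: `P_k = c |X_k|^2 / (fs * sum(w^2))` with
#' `c = 2` except at DC and Nyquist. Under this scaling
#' `sum(P) * df = sum((x w)^2) / sum(w^2)` (discrete Parseval identity).
#'
#' @param axis_signal numeric vector, length >= 256.
#' @param fs_hz sampling rate in Hz.
#' @param alpha Tukey cosine fraction (default 0.5).
#' @param band analysis band passed to [psd_estimate()].
#' @return a [psd_estimate()].
#' @export
periodogram_tukey <- function(axis_signal, fs_hz, alpha = 0.5, band = c(0.5, 15)) {
  x <- as.numeric(axis_signal)
  n <- length(x)
  if (n < 256L)
    gf_stop("gaitfall_invalid_input", "periodogram needs at least 256 samples")
  w <- tukey_window(n, alpha)
  X <- fft(x * w)
  n_half <- n %/% 2L + 1L
  p <- Mod(X[seq_len(n_half)])^2 / (fs_hz * sum(w^2))
  scale2 <- rep(2, n_half)
  scale2[1L] <- 1
  if (n %% 2L == 0L) scale2[n_half] <- 1
  psd_estimate(freqs_hz = (seq_len(n_half) - 1L) * fs_hz / n,
               power = p * scale2, band = band)
}

# Prominence of each local maximum of y (scipy definition): height above the
# higher of the two reference minima found walking left/right until a taller
# sample or the edge. Returns peaks with left/right base indices.
peak_prominences <- function(y) {
  n <- length(y)
  idx <- which(diff(sign(diff(y))) < 0) + 1L
  if (!length(idx))
    return(data.frame(index = integer(), prominence = numeric(),
                      left_base = integer(), right_base = integer()))
  np <- length(idx)
  prom <- numeric(np); lb <- integer(np); rb <- integer(np)
  for (k in seq_len(np)) {
    i <- idx[k]
    j <- i - 1L; min_l <- y[i]; base_l <- i
    while (j >= 1L && y[j] <= y[i]) {
      if (y[j] < min_l) { min_l <- y[j]; base_l <- j }
      j <- j - 1L
    }
    j <- i + 1L; min_r <- y[i]; base_r <- i
    while (j <= n && y[j] <= y[i]) {
      if (y[j] < min_r) { min_r <- y[j]; base_r <- j }
      j <- j + 1L
    }
    prom[k] <- y[i] - max(min_l, min_r)
    lb[k] <- base_l; rb[k] <- base_r
  }
  data.frame(index = idx, prominence = prom, left_base = lb, right_base = rb)
}

# Interpolated width (in samples) of peak i at height = y[peak] - 0.5*prom,
# confined to [left_base, right_base] (scipy peak_widths, rel_height = 0.5).
peak_width_half_prom <- function(y, index, prominence, left_base, right_base) {
  h <- y[index] - 0.5 * prominence
  # left crossing
  i <- index
  while (i > left_base && y[i - 1L] > h) i <- i - 1L
  left <- if (i > left_base && y[i - 1L] <= h)
    (i - 1L) + (h - y[i - 1L]) / (y[i] - y[i - 1L])
  else as.numeric(left_base)
  i <- index
  while (i < right_base && y[i + 1L] > h) i <- i + 1L
  right <- if (i < right_base && y[i + 1L] <= h)
    i + (y[i] - h) / (y[i] - y[i + 1L])
  else as.numeric(right_base)
  right - left
}

#' Two most prominent spectral peaks
#'
#' Local maxima of the in-band PSD ranked by prominence. For each of the two
#' most prominent peaks: frequency, amplitude (PSD value), width at half
#' prominence (Hz, linearly interpolated), and prominence. When fewer than
#' two local maxima exist the missing descriptor falls back to frequency 0
#' with zero amplitude, width and prominence.
#'
#' @param psd a [psd_estimate()].
#' @return named numeric vector `F1, AmpF1, wF1, pF1, F2, AmpF2, wF2, pF2`;
#'   F1 is the more prominent peak.
#' @export
dominant_peaks <- function(psd) {
  stopifnot(inherits(psd, "psd_estimate"))
  f <- psd$freqs_hz[psd$band_mask]
  y <- psd$power[psd$band_mask]
  df <- if (length(f) > 1L) f[2L] - f[1L] else 0
  pk <- peak_prominences(y)
  zero <- c(0, 0, 0, 0)
  desc <- function(row) {
    w <- peak_width_half_prom(y, row$index, row$prominence,
                              row$left_base, row$right_base) * df
    c(f[row$index], y[row$index], w, row$prominence)
  }
  if (nrow(pk) == 0L) {
    out <- c(zero, zero)
  } else {
    ord <- order(-pk$prominence, pk$index)
    first <- desc(pk[ord[1L], ])
    second <- if (nrow(pk) >= 2L) desc(pk[ord[2L], ]) else zero
    out <- c(first, second)
  }
  names(out) <- c("F1", "AmpF1", "wF1", "pF1", "F2", "AmpF2", "wF2", "pF2")
  out
}

#' The 32 frequency-domain features for one axis
#'
#' All computed on the 0.5–15 Hz band of the PSD: the two dominant-peak
#' descriptors (frequency, amplitude, width, prominence), audio-style shape
#' descriptors (centroid, spread, weighted skewness/kurtosis, flatness,
#' crest, decrease, slope, 95% rolloff, normalized entropy), summary
#' statistics of the power values and of the lower (0.5–7.75 Hz) and upper
#' (7.75–15 Hz) half-bands, relative power in 0.5–3, 3–8 and 8–15 Hz, total
#' band power, the F2/F1 amplitude ratio and the median frequency.
#'
#' @param psd a [psd_estimate()].
#' @return named numeric vector of length 32.
#' @export
freq_features_axis <- function(psd) {
  stopifnot(inherits(psd, "psd_estimate"))
  f <- psd$freqs_hz[psd$band_mask]
  p <- psd$power[psd$band_mask]
  if (sum(p) == 0)
    gf_stop("gaitfall_degenerate_spectrum", "all in-band power is zero")
  df <- f[2L] - f[1L]
  tot <- sum(p)
  pr <- p / tot
  centroid <- sum(f * pr)
  spread <- sqrt(sum((f - centroid)^2 * pr))
  skew_w <- if (spread == 0) 0 else sum((f - centroid)^3 * pr) / spread^3
  kurt_w <- if (spread == 0) 0 else sum((f - centroid)^4 * pr) / spread^4
  flat <- if (any(p == 0)) 0 else exp(mean(log(p))) / mean(p)
  crest <- max(p) / mean(p)
  k <- seq_along(p)
  decrease <- sum((p[-1L] - p[1L]) / (k[-1L] - 1)) / sum(p[-1L])
  slope <- sum((f - mean(f)) * (p - mean(p))) / sum((f - mean(f))^2)
  cum <- cumsum(p)
  rolloff <- f[which(cum >= 0.95 * tot)[1L]]
  medfreq <- f[which(cum >= 0.5 * tot)[1L]]
  nz <- pr[pr > 0]
  entropy <- if (length(p) > 1L) -sum(nz * log(nz)) / log(length(p)) else 0
  mid <- sum(psd$band) / 2     # 7.75 Hz for the 0.5-15 band
  fh <- f < mid
  peaks <- dominant_peaks(psd)
  band_power <- function(lo, hi) sum(p[f >= lo & f < hi]) / tot
  out <- c(
    peaks,
    centroid_PSD = centroid,
    spread_PSD = spread,
    skew_PSD = skew_w,
    kurt_PSD = kurt_w,
    flatness_PSD = flat,
    crest_PSD = crest,
    decrease_PSD = decrease,
    slope_PSD = slope,
    rolloff95 = rolloff,
    entropy_PSD = entropy,
    mean_PSD = mean(p),
    med_PSD = median(p),
    std_PSD = sd(p),
    max_PSD = max(p),
    mean_FH_PSD = mean(p[fh]),
    mean_LH_PSD = mean(p[!fh]),
    med_FH_PSD = median(p[fh]),
    med_LH_PSD = median(p[!fh]),
    relpow_0p5_3 = band_power(psd$band[1], 3),
    relpow_3_8 = band_power(3, 8),
    relpow_8_15 = sum(p[f >= 8 & f <= psd$band[2]]) / tot,
    power_total = tot * df,
    ratio_F2F1 = if (peaks[["AmpF1"]] > 0) peaks[["AmpF2"]] / peaks[["AmpF1"]] else 0,
    medfreq = medfreq
  )
  out
}
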