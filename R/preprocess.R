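#' Three-sample sliding median filter
#'
#' Suppresses isolated single-sample spikes before any linear filtering. The
#' window shrinks at the edges, so the first and last samples pass through
#' unchanged.
#'
#' @param signal numeric vector, length >= 3.
#' @return filtered vector of the same length.
#' @export
median_filter3 <- function(signal) {
  if (length(signal) < 3L)
    gf_stop("gaitfall_invalid_input", "median filter needs at least 3 samples")
  as.numeric(stats::runmed(signal, k = 3L, endrule = "keep"))
}

# Odd-reflection padding around both endpoints (scipy-style), so zero-phase
# IIR filtering sees no step at the record boundaries. Pad is trimmed after
# filtering.
reflect_pad <- function(x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  left <- 2 * x[1] - x[seq(pad + 1L, 2L)]
  right <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  list(x = c(left, x, right), pad = pad)
}

filtfilt_padded <- function(filt, x, pad) {
  p <- reflect_pad(x, as.integer(pad))
  y <- signal::filtfilt(filt, p$x)
  y[seq(p$pad + 1L, p$pad + length(x))]
}

#' Remove the gravitational component of an acceleration axis
#'
#' Estimates gravity as the output of a zero-phase order-2 Butterworth
#' low-pass at 0.25 Hz and subtracts it, leaving body acceleration. On the
#' vertical axis this removes the ~1 g offset; on all axes it removes slow
#' postural drift.
#'
#' @param signal numeric vector, length >= `2 * fs_hz`.
#' @param fs_hz sampling rate in Hz.
#' @param cutoff_hz gravity-estimate low-pass cutoff (default 0.25 Hz; any
#'   residual below 0.5 Hz is removed again by the bandpass high edge).
#' @return body acceleration, same length; mean is ~0.
#' @export
remove_gravity <- function(signal, fs_hz, cutoff_hz = 0.25) {
  if (length(signal) < 2 * fs_hz)
    gf_stop("gaitfall_invalid_input", "gravity removal needs at least 2 s of signal")
  lp <- signal::butter(2, cutoff_hz / (fs_hz / 2), type = "low")
  # low-pass the mean-removed signal so a constant input is handled exactly
  centered <- signal - mean(signal)
  gravity <- filtfilt_padded(lp, centered, pad = round(3 * fs_hz / cutoff_hz))
  out <- centered - gravity
  out - mean(out)
}

#' Zero-phase Butterworth bandpass
#'
#' Order-4 Butterworth band design applied forward and backward
#' (`signal::filtfilt`) with odd-reflection padding, so the magnitude response
#' is squared and the phase response is zero: peak positions are preserved.
#'
#' @param signal numeric vector.
#' @param fs_hz sampling rate in Hz.
#' @param lo_hz,hi_hz band edges, `0 < lo_hz < hi_hz < fs_hz/2`.
#' @return filtered vector of the same length.
#' @export
bandpass <- function(signal, fs_hz, lo_hz, hi_hz) {
  if (!(lo_hz > 0 && lo_hz < hi_hz && hi_hz < fs_hz / 2))
    gf_stop("gaitfall_invalid_input",
            "invalid band (%g, %g) Hz at fs = %g Hz", lo_hz, hi_hz, fs_hz)
  bp <- signal::butter(4, c(lo_hz, hi_hz) / (fs_hz / 2), type = "pass")
  filtfilt_padded(bp, signal, pad = round(3 * fs_hz / lo_hz))
}

#' Normalize a signal to its maximum absolute value
#'
#' @param signal numeric vector with at least one nonzero sample.
#' @return `signal / max(abs(signal))`; max absolute value is exactly 1.
#' @export
normalize_max <- function(signal) {
  m <- max(abs(signal))
  if (m == 0)
    gf_stop("gaitfall_degenerate_signal", "cannot max-normalize an all-zero signal")
  signal / m
}

#' Preprocess a tri-axial recording
#'
#' Per axis: 3-sample median filter, gravity removal, then two zero-phase
#' bandpass versions — 0.5–3 Hz (`band_step`, used only for step detection)
#' and 0.5–15 Hz (`band_analysis`, used for every feature) — each
#' max-normalized per axis.
#'
#' @param rec a [triaxial_recording()].
#' @return an object of class `preprocessed_recording` with elements `fs_hz`,
#'   `band_step` and `band_analysis` (both n x 3 matrices, columns V/ML/AP).
#' @export
preprocess_recording <- function(rec) {
  stopifnot(inherits(rec, "triaxial_recording"))
  fs <- rec$fs_hz
  one_axis <- function(x, axis) {
    body <- remove_gravity(median_filter3(x), fs)
    res <- tryCatch(
      list(step = normalize_max(bandpass(body, fs, 0.5, 3)),
           analysis = normalize_max(bandpass(body, fs, 0.5, 15))),
      gaitfall_degenerate_signal = function(e)
        gf_stop("gaitfall_degenerate_signal",
                "axis %s of subject %s is degenerate (all-zero after filtering)",
                axis, rec$subject_id)
    )
    res
  }
  per_axis <- lapply(seq_len(3L), function(j) one_axis(rec$samples[, j], axis_names()[j]))
  band_step <- vapply(per_axis, `[[`, numeric(nrow(rec$samples)), "step")
  band_analysis <- vapply(per_axis, `[[`, numeric(nrow(rec$samples)), "analysis")
  colnames(band_step) <- colnames(band_analysis) <- axis_names()
  structure(
    list(fs_hz = fs, band_step = band_step, band_analysis = band_analysis,
         subject_id = rec$subject_id),
    class = "preprocessed_recording"
  )
}
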