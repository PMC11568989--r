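#' Detect steps from the vertical-axis step-band signal
#'
#' Steps are local maxima of the max-normalized 0.5–3 Hz vertical
#' acceleration. Candidate maxima below a height threshold are dropped, and
#' close pairs are resolved greedily by descending height under a minimum
#' peak separation, so multi-lobed step peaks are not double counted.
#'
#' Peak-to-peak intervals give step durations; consecutive non-overlapping
#' pairs of step durations give stride durations. Intervals outside the
#' physiological range (0.25–2.5 s) are excluded from the duration statistics
#' while the peak indices themselves are retained.
#'
#' @param v_band_step max-normalized 0.5–3 Hz vertical-axis signal.
#' @param fs_hz sampling rate in Hz.
#' @param min_height minimum peak height on the normalized signal (default 0.2).
#' @param min_dist_s minimum peak separation in seconds (default 0.25,
#'   supporting cadences up to 240 steps/min).
#' @return an object of class `step_segmentation` with `peak_indices`
#'   (1-based), `step_durations_s`, `stride_durations_s` and `cadence_spm`.
#' @export
detect_steps <- function(v_band_step, fs_hz, min_height = 0.2, min_dist_s = 0.25) {
  x <- as.numeric(v_band_step)
  n <- length(x)
  if (n < 10 * fs_hz)
    gf_stop("gaitfall_invalid_input", "step detection needs at least 10 s of signal")
  # strict local maxima above threshold
  cand <- which(x[-c(1L, n)] > x[-c(n - 1L, n)] & x[-c(1L, n)] >= x[-c(1L, 2L)]) + 1L
  cand <- cand[x[cand] >= min_height]
  # enforce minimum distance, keeping taller peaks first (deterministic:
  # ties by earlier index)
  min_dist <- round(min_dist_s * fs_hz)
  keep <- logical(length(cand))
  alive <- rep(TRUE, length(cand))
  ord <- order(-x[cand], cand)
  for (i in ord) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[abs(cand - cand[i]) < min_dist] <- FALSE
  }
  peaks <- sort(cand[keep])
  if (length(peaks) < 8L)
    gf_stop("gaitfall_no_steps", "fewer than 8 step peaks detected")
  intervals <- diff(peaks) / fs_hz
  ok <- intervals > 0.25 & intervals < 2.5
  step_dur <- intervals[ok]
  if (length(step_dur) < 1L)
    gf_stop("gaitfall_no_steps", "no plausible step durations")
  n_str <- length(step_dur) %/% 2L
  stride_dur <- if (n_str > 0L)
    step_dur[seq(1L, by = 2L, length.out = n_str)] +
    step_dur[seq(2L, by = 2L, length.out = n_str)]
  else numeric(0)
  structure(
    list(peak_indices = peaks,
         step_durations_s = step_dur,
         stride_durations_s = stride_dur,
         cadence_spm = 60 / mean(step_dur),
         fs_hz = fs_hz),
    class = "step_segmentation"
  )
}

#' @export
print.step_segmentation <- function(x, ...) {
  cat(sprintf("<step_segmentation> %d peaks, mean step %.3f s, cadence %.1f spm\n",
              length(x$peak_indices), mean(x$step_durations_s), x$cadence_spm))
  invisible(x)
}

#' Gait-cycle timing features
#'
#' The three vertical-axis-only basic gait measures: average step duration,
#' average stride duration, and cadence in steps per minute.
#'
#' @param seg a [detect_steps()] segmentation.
#' @return named numeric vector `avg_step_dur_s`, `avg_stride_dur_s`,
#'   `cadence_spm`.
#' @export
gait_cycle_features <- function(seg) {
  stopifnot(inherits(seg, "step_segmentation"))
  c(avg_step_dur_s = mean(seg$step_durations_s),
    avg_stride_dur_s = if (length(seg$stride_durations_s)) mean(seg$stride_durations_s) else NA_real_,
    cadence_spm = seg$cadence_spm)
}
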