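#' Gait signal profile for the synthetic generator
#'
#' Parameterizes one subject's quasi-periodic walking acceleration. The
#' signal model is a harmonic series on the stride frequency
#' (`f_step_hz / 2`): per axis, amplitudes for stride-harmonics 1..4, so
#' harmonic 2 is the step frequency. Standard waist-accelerometer
#' biomechanics: vertical (V) and anterior-posterior (AP) power concentrates
#' at the step frequency, mediolateral (ML) at the stride frequency.
#' Step-to-step timing and amplitude jitter, additive white noise, and a 1 g
#' gravity offset on V complete the model.
#'
#' @param f_step_hz mean step frequency in Hz (cohort draws default to
#'   U\[1.6, 2.1\], a normal self-selected walking pace).
#' @param harmonic_amps 3 x 4 matrix (rows V, ML, AP) of amplitudes in g for
#'   stride-harmonics 1..4.
#' @param timing_jitter sd of the per-step period perturbation, as a
#'   fraction of the period.
#' @param amp_jitter sd of the per-step amplitude scaling.
#' @param noise_sd additive white noise sd in g.
#' @param gravity_v constant V offset in g (default 1).
#' @return list of class `gait_profile`.
#' @export
gait_profile <- function(f_step_hz = 1.9,
                         harmonic_amps = default_harmonics(),
                         timing_jitter = 0.02, amp_jitter = 0.05,
                         noise_sd = 0.02, gravity_v = 1.0) {
  stopifnot(f_step_hz >= 1.0, f_step_hz <= 3.0,
            timing_jitter >= 0, amp_jitter >= 0, noise_sd >= 0,
            is.matrix(harmonic_amps), nrow(harmonic_amps) == 3L,
            ncol(harmonic_amps) == 4L)
  structure(list(f_step_hz = f_step_hz, harmonic_amps = harmonic_amps,
                 timing_jitter = timing_jitter, amp_jitter = amp_jitter,
                 noise_sd = noise_sd, gravity_v = gravity_v),
            class = "gait_profile")
}

#' @rdname gait_profile
#' @export
default_harmonics <- function() {
  m <- rbind(V = c(0.05, 0.50, 0.05, 0.15),
             ML = c(0.40, 0.08, 0.05, 0.02),
             AP = c(0.12, 0.35, 0.06, 0.10))
  colnames(m) <- paste0("h", 1:4)
  m
}

#' Generate one synthetic walking recording
#'
#' Step periods are drawn as `(1/f_step) * (1 + e_k)` with
#' `e_k ~ N(0, timing_jitter)`; within step k the stride phase advances
#' linearly by half a stride cycle, so harmonic 2 completes one cycle per
#' step. Each step carries a common amplitude scale `1 + N(0, amp_jitter)`
#' across axes and harmonics. Axis phases are drawn once per subject.
#' Deterministic given `seed`.
#'
#' @param profile a [gait_profile()].
#' @param duration_s recording length in seconds (default 60, the standard
#'   clinic walk).
#' @param fs_hz sampling rate (default 100).
#' @param seed integer seed.
#' @param subject_id,label metadata for the returned recording.
#' @return a [triaxial_recording()].
#' @export
generate_subject <- function(profile, duration_s = 60, fs_hz = 100, seed = 1L,
                             subject_id = "synthetic", label = "unknown") {
  stopifnot(inherits(profile, "gait_profile"))
  with_seed(seed, {
    n <- round(duration_s * fs_hz)
    t <- (seq_len(n) - 1L) / fs_hz
    period <- 1 / profile$f_step_hz
    n_steps <- ceiling(duration_s / period * 1.5) + 4L
    periods <- period * (1 + rnorm(n_steps, 0, profile$timing_jitter))
    periods <- pmax(periods, 0.25 * period)
    bounds <- c(0, cumsum(periods))
    amp_scale <- 1 + rnorm(n_steps, 0, profile$amp_jitter)
    step_of <- findInterval(t, bounds, rightmost.closed = FALSE)
    # stride phase: advances by pi (half a stride cycle) per step
    frac <- (t - bounds[step_of]) / periods[step_of]
    phase <- pi * (step_of - 1 + frac)
    phases0 <- matrix(runif(12, 0, 2 * pi), nrow = 3L)
    samples <- vapply(1:3, function(ax) {
      sig <- numeric(n)
      for (h in 1:4)
        sig <- sig + profile$harmonic_amps[ax, h] * cos(h * phase + phases0[ax, h])
      sig <- sig * amp_scale[step_of] + rnorm(n, 0, profile$noise_sd)
      if (ax == 1L) sig <- sig + profile$gravity_v
      sig
    }, numeric(n))
    triaxial_recording(subject_id, fs_hz, samples, label)
  })
}

#' Cohort specification for the synthetic generator
#'
#' Defaults mirror the reference study's cohort shape (35 fallers, 38
#' non-fallers, one-minute walks at 100 Hz) with fallers drawn from a
#' higher-jitter, lower-regularity regime (timing/amplitude jitter 8%/15%)
#' than non-fallers (2%/5%).
#'
#' @param n_fallers,n_nonfallers class sizes (each >= 2).
#' @param duration_s recording length (>= 10 s).
#' @param fs_hz sampling rate.
#' @param faller_profile,nonfaller_profile functions `(f_step_hz)` returning
#'   a [gait_profile()]; defaults implement the jitter regimes above.
#' @param f_step_range step-frequency draw range in Hz.
#' @param seed cohort seed; per-subject seeds are derived from it.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_fallers = 35L, n_nonfallers = 38L,
                        duration_s = 60, fs_hz = 100,
                        faller_profile = function(f)
                          gait_profile(f, timing_jitter = 0.08, amp_jitter = 0.15),
                        nonfaller_profile = function(f)
                          gait_profile(f, timing_jitter = 0.02, amp_jitter = 0.05),
                        f_step_range = c(1.6, 2.1), seed = 1L) {
  stopifnot(n_fallers >= 2L, n_nonfallers >= 2L, duration_s >= 10)
  structure(list(n_fallers = as.integer(n_fallers),
                 n_nonfallers = as.integer(n_nonfallers),
                 duration_s = duration_s, fs_hz = fs_hz,
                 faller_profile = faller_profile,
                 nonfaller_profile = nonfaller_profile,
                 f_step_range = f_step_range, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a labeled synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @return list of [triaxial_recording()] (non-fallers first), length
#'   `n_fallers + n_nonfallers`; regenerating with the same spec is
#'   bitwise-identical.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  make <- function(i, label) {
    sseed <- derive_seed(spec$seed, i)
    f_step <- with_seed(derive_seed(sseed, 1L),
                        runif(1, spec$f_step_range[1], spec$f_step_range[2]))
    prof <- if (label == "faller") spec$faller_profile(f_step)
            else spec$nonfaller_profile(f_step)
    generate_subject(prof, spec$duration_s, spec$fs_hz, seed = sseed,
                     subject_id = sprintf("S%03d", i), label = label)
  }
  c(lapply(seq_len(spec$n_nonfallers), make, label = "non_faller"),
    lapply(spec$n_nonfallers + seq_len(spec$n_fallers), make, label = "faller"))
}
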