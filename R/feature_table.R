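time_feature_names <- function() c(
  "mean", "std", "skew", "kurt", "rms", "range", "median", "iqr",
  "mean_FH", "mean_LH", "std_FH", "std_LH", "zcr", "energy", "mav", "mad",
  "cv_peak_amp", "StpReg", "StrReg", "reg_ratio", "meanTrend"
)

freq_feature_names <- function() c(
  "F1", "AmpF1", "wF1", "pF1", "F2", "AmpF2", "wF2", "pF2",
  "centroid_PSD", "spread_PSD", "skew_PSD", "kurt_PSD", "flatness_PSD",
  "crest_PSD", "decrease_PSD", "slope_PSD", "rolloff95", "entropy_PSD",
  "mean_PSD", "med_PSD", "std_PSD", "max_PSD", "mean_FH_PSD", "mean_LH_PSD",
  "med_FH_PSD", "med_LH_PSD", "relpow_0p5_3", "relpow_3_8", "relpow_8_15",
  "power_total", "ratio_F2F1", "medfreq"
)

#' The canonical feature registry
#'
#' Fixed, deterministic order of all 168 feature names: 3 gait-cycle
#' features, 6 cross-axis correlation/covariance features, then 21
#' time-domain and 32 frequency-domain features per axis, suffixed `_V`,
#' `_ML`, `_AP`. The decomposition 168 = 3 + 6 + 3x21 + 3x32 is asserted at
#' every call.
#'
#' @return character vector of length 168.
#' @export
feature_registry <- function() {
  gait <- c("avg_step_dur_s", "avg_stride_dur_s", "cadence_spm")
  cross <- c("corr_V_ML", "corr_AP_ML", "corr_V_AP",
             "cov_V_ML", "cov_AP_ML", "cov_V_AP")
  per_axis <- unlist(lapply(axis_names(), function(a)
    paste0(c(time_feature_names(), freq_feature_names()), "_", a)))
  reg <- c(gait, cross, per_axis)
  stopifnot(length(reg) == 3L + 6L + 3L * (21L + 32L), !anyDuplicated(reg))
  reg
}

#' Extract the 168-feature vector for one recording
#'
#' Runs the full per-subject pipeline: preprocessing, vertical-axis step
#' detection on the 0.5–3 Hz band, then gait-cycle, cross-axis, time-domain
#' and frequency-domain features on the 0.5–15 Hz band.
#'
#' @param rec a [triaxial_recording()].
#' @return named numeric vector of length 168 in [feature_registry()] order.
#' @export
extract_features <- function(rec) {
  stopifnot(inherits(rec, "triaxial_recording"))
  pp <- preprocess_recording(rec)
  seg <- tryCatch(
    detect_steps(pp$band_step[, "V"], pp$fs_hz),
    gaitfall_no_steps = function(e)
      gf_stop("gaitfall_no_steps", "subject %s: %s", rec$subject_id, conditionMessage(e))
  )
  ba <- pp$band_analysis
  per_axis <- lapply(axis_names(), function(a) {
    tf <- time_features_axis(ba[, a], seg, pp$fs_hz)
    ff <- freq_features_axis(periodogram_tukey(ba[, a], pp$fs_hz))
    out <- c(tf, ff)
    names(out) <- paste0(c(time_feature_names(), freq_feature_names()), "_", a)
    out
  })
  vec <- c(gait_cycle_features(seg),
           cross_axis_features(ba[, "V"], ba[, "ML"], ba[, "AP"]),
           unlist(per_axis))
  vec <- vec[feature_registry()]
  if (!all(is.finite(vec)))
    gf_stop("gaitfall_invalid_input", "subject %s: non-finite features: %s",
            rec$subject_id, paste(names(vec)[!is.finite(vec)], collapse = ","))
  vec
}

#' Build a labeled cohort feature matrix
#'
#' Extracts features for every recording; subjects whose extraction fails
#' (degenerate axis, too few steps) are excluded with a logged reason rather
#' than aborting the cohort.
#'
#' @param cohort list of [triaxial_recording()]; at least 4 subjects with
#'   both classes present.
#' @return object of class `feature_matrix`: list with `X` (subjects x 168),
#'   `subject_ids`, `labels` (factor, positive class `faller`), `excluded`
#'   (data.frame of subject_id, reason).
#' @export
build_matrix <- function(cohort) {
  if (length(cohort) < 4L)
    gf_stop("gaitfall_cohort_invalid", "need at least 4 subjects")
  rows <- list(); ids <- character(); labs <- character()
  excl <- data.frame(subject_id = character(), reason = character())
  for (rec in cohort) {
    v <- tryCatch(extract_features(rec), gaitfall_error = function(e) e)
    if (inherits(v, "condition")) {
      excl <- rbind(excl, data.frame(subject_id = rec$subject_id,
                                     reason = conditionMessage(v)))
    } else {
      rows[[length(rows) + 1L]] <- v
      ids <- c(ids, rec$subject_id)
      labs <- c(labs, rec$label)
    }
  }
  X <- do.call(rbind, rows)
  rownames(X) <- ids
  labels <- factor(labs, levels = c("non_faller", "faller"))
  if (length(unique(labs[labs != "unknown"])) < 2L)
    gf_stop("gaitfall_cohort_invalid", "a class is absent after exclusions")
  structure(list(X = X, subject_ids = ids, labels = labels, excluded = excl),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d subjects x %d features (%d faller / %d non-faller), %d excluded\n",
              nrow(x$X), ncol(x$X), sum(x$labels == "faller", na.rm = TRUE),
              sum(x$labels == "non_faller", na.rm = TRUE), nrow(x$excluded)))
  invisible(x)
}

#' Fit min-max scaling parameters on a matrix
#'
#' @param X numeric matrix (rows = subjects).
#' @return list with `min` and `range` per column (constant columns get
#'   range 1 so they map to 0).
#' @export
minmax_fit <- function(X) {
  mins <- apply(X, 2L, min)
  maxs <- apply(X, 2L, max)
  rng <- maxs - mins
  rng[rng == 0] <- 1
  list(min = mins, range = rng)
}

#' Apply stored min-max parameters
#'
#' @param X numeric matrix.
#' @param params from [minmax_fit()] (fit on training folds only, to keep
#'   held-out folds untouched by test-set statistics).
#' @return scaled matrix; training columns land in \[0, 1\], constant
#'   columns at 0. Held-out values may fall slightly outside \[0, 1\].
#' @export
minmax_apply <- function(X, params) {
  sweep(sweep(X, 2L, params$min, "-"), 2L, params$range, "/")
}

#' Min-max scale a feature matrix to \[0, 1\]
#'
#' @param fm a [build_matrix()] result (or plain matrix).
#' @return same structure with `X` scaled and the fit parameters attached as
#'   `scaling`.
#' @export
minmax_scale <- function(fm) {
  X <- if (inherits(fm, "feature_matrix")) fm$X else as.matrix(fm)
  if (nrow(X) < 2L)
    gf_stop("gaitfall_invalid_input", "min-max scaling needs >= 2 subjects")
  params <- minmax_fit(X)
  Xs <- minmax_apply(X, params)
  if (inherits(fm, "feature_matrix")) {
    fm$X <- Xs
    fm$scaling <- params
    fm
  } else Xs
}

#' Write / read a cohort feature table
#'
#' CSV with header `subject_id,label,<feature names>` in registry order;
#' round-trip safe.
#' @param fm a `feature_matrix`.
#' @param path CSV path.
#' @export
write_features_csv <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- data.frame(subject_id = fm$subject_ids, label = as.character(fm$labels),
                   fm$X, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  X <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(X) <- df$subject_id
  structure(list(X = X, subject_ids = df$subject_id,
                 labels = factor(df$label, levels = c("non_faller", "faller")),
                 excluded = data.frame(subject_id = character(), reason = character())),
            class = "feature_matrix")
}
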