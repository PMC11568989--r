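#' Construct a tri-axial accelerometer recording
#'
#' One subject's raw waist-worn accelerometer signal: an n x 3 matrix of
#' acceleration in g with columns ordered vertical (V), mediolateral (ML),
#' anterior-posterior (AP), plus the sampling rate and the faller label.
#'
#' @param subject_id character scalar identifying the subject.
#' @param fs_hz sampling rate in Hz; must exceed 30 Hz so that the 15 Hz
#'   analysis band edge is below Nyquist. The reference cohort used 100 Hz.
#' @param samples numeric n x 3 matrix in g, columns `(V, ML, AP)`; at least
#'   10 s of signal (`n >= 10 * fs_hz`), all values finite.
#' @param label one of `"faller"`, `"non_faller"`, `"unknown"`.
#' @return an object of class `triaxial_recording`.
#' @export
triaxial_recording <- function(subject_id, fs_hz, samples, label = "unknown") {
  label <- match.arg(label, c("faller", "non_faller", "unknown"))
  samples <- as.matrix(samples)
  if (!is.numeric(samples) || ncol(samples) != 3L)
    gf_stop("gaitfall_invalid_input", "samples must be a numeric n x 3 matrix (V, ML, AP)")
  if (!all(is.finite(samples)))
    gf_stop("gaitfall_invalid_input", "samples contain non-finite values (subject %s)", subject_id)
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || fs_hz <= 30)
    gf_stop("gaitfall_invalid_input", "fs_hz must be a single value > 30 Hz")
  if (nrow(samples) < 10 * fs_hz)
    gf_stop("gaitfall_invalid_input",
            "recording too short: %d samples < 10 s at %g Hz (subject %s)",
            nrow(samples), fs_hz, subject_id)
  colnames(samples) <- c("V", "ML", "AP")
  structure(
    list(subject_id = as.character(subject_id), fs_hz = fs_hz,
         samples = samples, label = label),
    class = "triaxial_recording"
  )
}

#' @export
print.triaxial_recording <- function(x, ...) {
  cat(sprintf("<triaxial_recording> subject %s: %.1f s at %g Hz, label %s\n",
              x$subject_id, nrow(x$samples) / x$fs_hz, x$fs_hz, x$label))
  invisible(x)
}

axis_names <- function() c("V", "ML", "AP")

#' Read a tri-axial signal file
#'
#' Accepts delimited text with a `time,v,ml,ap` header (the time column is
#' ignored; timing comes from the manifest sampling rate) or a headerless
#' three-column `v,ml,ap` file.
#'
#' @param path file path.
#' @param subject_id,fs_hz,label metadata, normally from the cohort manifest.
#' @return a [triaxial_recording()].
#' @export
read_signal_csv <- function(path, subject_id, fs_hz, label = "unknown") {
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", first)
  df <- read.csv(path, header = has_header)
  if (has_header) {
    names(df) <- tolower(names(df))
    need <- c("v", "ml", "ap")
    if (!all(need %in% names(df)))
      gf_stop("gaitfall_invalid_input",
              "header must contain columns v, ml, ap (got: %s)", paste(names(df), collapse = ","))
    mat <- as.matrix(df[, need])
  } else {
    if (ncol(df) != 3L)
      gf_stop("gaitfall_invalid_input", "headerless signal file must have exactly 3 columns")
    mat <- as.matrix(df)
  }
  triaxial_recording(subject_id, fs_hz, mat, label)
}

#' Write a tri-axial recording to CSV
#'
#' Writes `time,v,ml,ap` with time in seconds; round-trips through
#' [read_signal_csv()].
#' @param rec a [triaxial_recording()].
#' @param path output file path.
#' @export
write_signal_csv <- function(rec, path) {
  stopifnot(inherits(rec, "triaxial_recording"))
  n <- nrow(rec$samples)
  df <- data.frame(time = (seq_len(n) - 1) / rec$fs_hz,
                   v = rec$samples[, 1], ml = rec$samples[, 2], ap = rec$samples[, 3])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort manifest
#'
#' A CSV with columns `subject_id,path,fs_hz,label` listing one signal file
#' per subject. Relative paths are resolved against the manifest's directory.
#'
#' @param path manifest CSV path.
#' @return list of [triaxial_recording()] objects.
#' @export
read_cohort_manifest <- function(path) {
  man <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "path", "fs_hz", "label")
  if (!all(need %in% names(man)))
    gf_stop("gaitfall_invalid_input", "manifest must have columns %s", paste(need, collapse = ","))
  base <- dirname(normalizePath(path))
  lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    read_signal_csv(p, man$subject_id[i], man$fs_hz[i], man$label[i])
  })
}

#' Write a cohort of recordings and its manifest
#'
#' @param cohort list of [triaxial_recording()].
#' @param dir output directory (created if missing).
#' @return the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(rec) {
    f <- paste0(rec$subject_id, ".csv")
    write_signal_csv(rec, file.path(dir, f))
    data.frame(subject_id = rec$subject_id, path = f,
               fs_hz = rec$fs_hz, label = rec$label)
  })
  man <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.csv")
  write.csv(man, mp, row.names = FALSE)
  invisible(mp)
}
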