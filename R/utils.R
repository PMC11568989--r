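#' @keywords internal
#' @noRd
gf_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "gaitfall_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals never disturb the
#' caller's RNG stream.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and an index, staying inside the
# positive 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483587L) + 1L
}

#' Area under the ROC curve from scores
#'
#' Mann-Whitney formulation: probability that a random positive scores above a
#' random negative, ties counted 1/2.
#'
#' @param scores numeric scores, larger = more faller-like.
#' @param labels logical or 0/1, `TRUE`/1 = faller (positive class).
#' @return AUC in \[0, 1\].
#' @export
auc_scores <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    gf_stop("gaitfall_undefined_metric", "AUC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
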