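#' ReliefF feature weights for a two-class cohort
#'
#' Deterministic all-instances ReliefF: every subject in turn is the query
#' instance; its K nearest same-class neighbors (hits, never itself) and K
#' nearest other-class neighbors (misses) under Manhattan distance over all
#' features move each feature's weight down by the mean hit difference and up
#' by the prior-weighted mean miss difference:
#'
#' `W[f] <- W[f] - sum_hits diff(f)/(m K) + P(miss class)/(1 - P(own class))
#'  * sum_miss diff(f)/(m K)`
#'
#' with `diff` the absolute value difference (features are expected on a
#' common \[0, 1\] scale, so `diff` is range-normalized) and `m` the number
#' of subjects. Distance ties are broken by ascending subject index, so the
#' result is a pure function of the data.
#'
#' When a class is too small to supply K hits or misses the neighbor count
#' is capped at what is available (with the matching divisor), the usual
#' convention that lets the K sweep run past the smaller class size.
#'
#' @param fm a [build_matrix()] result (scaled, see [minmax_scale()]) or a
#'   plain numeric matrix plus `labels`.
#' @param K neighbor count; each class must have at least 2 members.
#' @param labels optional factor/character when `fm` is a plain matrix.
#' @return object of class `relieff_result`: `K`, `weights` (named, in
#'   \[-1, 1\] for \[0, 1\]-scaled features), `ranking` (feature names by
#'   descending weight, ties by registry order).
#' @export
relieff_weights <- function(fm, K, labels = NULL) {
  if (inherits(fm, "feature_matrix")) {
    X <- fm$X; y <- fm$labels
  } else {
    X <- as.matrix(fm); y <- labels
  }
  y <- as.character(y)
  m <- nrow(X)
  cls <- table(y)
  if (length(cls) != 2L)
    gf_stop("gaitfall_cohort_invalid", "ReliefF needs exactly 2 classes, got %d", length(cls))
  if (K < 1L)
    gf_stop("gaitfall_invalid_K", "K must be >= 1")
  if (min(cls) < 2L)
    gf_stop("gaitfall_invalid_K", "each class needs >= 2 members for ReliefF")
  prior <- cls / m
  D <- as.matrix(stats::dist(X, method = "manhattan"))
  W <- numeric(ncol(X))
  for (i in seq_len(m)) {
    same <- which(y == y[i]); same <- same[same != i]
    other <- which(y != y[i])
    kh <- min(K, length(same))
    km <- min(K, length(other))
    hits <- same[order(D[i, same], same)][seq_len(kh)]
    misses <- other[order(D[i, other], other)][seq_len(km)]
    dh <- abs(sweep(X[hits, , drop = FALSE], 2L, X[i, ], "-"))
    dm <- abs(sweep(X[misses, , drop = FALSE], 2L, X[i, ], "-"))
    other_class <- setdiff(names(cls), y[i])
    w_miss <- prior[[other_class]] / (1 - prior[[y[i]]])
    W <- W - colSums(dh) / (m * kh) + w_miss * colSums(dm) / (m * km)
  }
  names(W) <- colnames(X)
  structure(
    list(K = K, weights = W,
         ranking = colnames(X)[order(-W)]),   # stable: ties keep column order
    class = "relieff_result"
  )
}

#' Top-N features of a ReliefF ranking
#'
#' @param result a [relieff_weights()] result.
#' @param N number of features to retain, `1 <= N <= length(weights)`.
#' @return character vector: the first `N` names of the ranking. Nested by
#'   construction: `top_n(N)` is a prefix of `top_n(N + 1)`.
#' @export
top_n <- function(result, N) {
  stopifnot(inherits(result, "relieff_result"))
  if (N < 1L || N > length(result$weights))
    gf_stop("gaitfall_invalid_input", "N = %d outside [1, %d]", N, length(result$weights))
  result$ranking[seq_len(N)]
}

#' The two-dimensional (K, N) feature-selection sweep
#'
#' For each neighbor count K in `K_range` the ReliefF weighting is computed
#' once; for each retained-feature count N in `N_range` the top-N subset is
#' handed to `eval_fn` for classifier evaluation. The default grid is
#' K = 1..40 by N = 5..40: 40 distinct weightings and 1440 evaluated cells.
#'
#' @param fm scaled `feature_matrix`.
#' @param K_range integer neighbor counts (default `1:40`).
#' @param N_range integer retained-feature counts (default `5:40`).
#' @param eval_fn function `(fm_subset, K, N)` returning a data.frame of
#'   evaluation rows (one per classifier configuration), e.g. a wrapper over
#'   [cross_validate()]. Defaults to [make_eval_fn()]'s MLP evaluator.
#' @param ... passed to [make_eval_fn()] when `eval_fn` is `NULL`.
#' @return object of class `selection_sweep`: `grid` (data.frame with K, N,
#'   evaluation columns, plus `skipped`), `weightings` (list of
#'   `relieff_result` per K).
#' @export
selection_sweep <- function(fm, K_range = 1:40, N_range = 5:40,
                            eval_fn = NULL, ...) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!length(K_range) || any(K_range < 1L))
    gf_stop("gaitfall_invalid_input", "K_range must be nonempty positive integers")
  if (any(N_range < 1L) || any(N_range > ncol(fm$X)))
    gf_stop("gaitfall_invalid_input", "N_range outside [1, %d]", ncol(fm$X))
  if (is.null(eval_fn)) eval_fn <- make_eval_fn(...)
  weightings <- vector("list", length(K_range))
  names(weightings) <- as.character(K_range)
  rows <- list()
  for (ki in seq_along(K_range)) {
    K <- K_range[ki]
    res <- tryCatch(relieff_weights(fm, K), gaitfall_invalid_K = function(e) e)
    if (inherits(res, "condition")) {
      rows[[length(rows) + 1L]] <- data.frame(K = K, N = N_range, skipped = TRUE)
      next
    }
    weightings[[ki]] <- res
    for (N in N_range) {
      sub <- fm
      sub$X <- fm$X[, top_n(res, N), drop = FALSE]
      ev <- eval_fn(sub, K, N)
      rows[[length(rows) + 1L]] <- cbind(data.frame(K = K, N = N), ev,
                                         data.frame(skipped = FALSE))
    }
  }
  grid <- do.call(rbind, lapply(rows, function(r) {
    # align columns across skipped / evaluated rows
    miss <- setdiff(c("K", "N", "hidden_units", "AUC", "accuracy", "sensitivity",
                      "specificity", "TP", "FN", "FP", "TN", "skipped"), names(r))
    for (col in miss) r[[col]] <- NA
    r[, c("K", "N", "hidden_units", "AUC", "accuracy", "sensitivity",
          "specificity", "TP", "FN", "FP", "TN", "skipped")]
  }))
  rownames(grid) <- NULL
  structure(list(grid = grid, weightings = weightings,
                 K_range = K_range, N_range = N_range),
            class = "selection_sweep")
}

#' Write the sweep grid to CSV
#'
#' Columns mirror the classification results table: K, N, hidden_units,
#' AUC, accuracy, sensitivity, specificity, TP, FN, FP, TN.
#' @param sweep a [selection_sweep()] result (or its `grid`).
#' @param path CSV path.
#' @export
write_grid_csv <- function(sweep, path) {
  grid <- if (inherits(sweep, "selection_sweep")) sweep$grid else sweep
  write.csv(grid[!grid$skipped, setdiff(names(grid), "skipped")],
            path, row.names = FALSE)
  invisible(path)
}
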