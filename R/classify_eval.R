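#' MLP configuration
#'
#' Training hyperparameters of the faller/non-faller perceptron: one ReLU
#' hidden layer, sigmoid output scoring the faller class, L2 penalty
#' `l2_alpha`, a hard epoch cap, and a stochastic gradient-based optimizer
#' (Adam by default; `solver = "sgd"` selects Nesterov-momentum SGD).
#' Remaining optimizer constants follow the common reference defaults:
#' learning rate 0.001, batch size `min(200, n)`, Adam betas 0.9/0.999,
#' loss-improvement tolerance 1e-4 over 10 epochs.
#'
#' @param hidden_units hidden layer width (the sweep default is
#'   `seq(10, 200, by = 10)`).
#' @param l2_alpha L2 regularization strength (default 1e-4).
#' @param max_epochs epoch cap (default 200).
#' @param solver `"adam"` or `"sgd"`.
#' @param learning_rate step size (default 1e-3).
#' @param seed integer seed for weight initialization and batch shuffling.
#' @return a list of class `mlp_config`.
#' @export
mlp_config <- function(hidden_units = 50L, l2_alpha = 1e-4, max_epochs = 200L,
                       solver = c("adam", "sgd"), learning_rate = 1e-3,
                       seed = 1L) {
  solver <- match.arg(solver)
  stopifnot(hidden_units >= 1L, l2_alpha > 0, max_epochs >= 1L)
  structure(list(hidden_units = as.integer(hidden_units), l2_alpha = l2_alpha,
                 max_epochs = as.integer(max_epochs), solver = solver,
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "mlp_config")
}

#' Train the MLP scorer
#'
#' @param X numeric matrix of scaled features (rows = subjects).
#' @param y labels: factor/character with positive class `"faller"`, or
#'   logical/0-1.
#' @param cfg an [mlp_config()].
#' @return object of class `mlp_model`; use [predict.mlp_model()] for
#'   continuous faller scores (`type = "score"`) or 0.5-threshold classes.
#' @export
train_mlp <- function(X, y, cfg = mlp_config()) {
  X <- as.matrix(X)
  y01 <- if (is.numeric(y) || is.logical(y)) as.numeric(y)
         else as.numeric(as.character(y) == "faller")
  if (length(unique(y01)) < 2L)
    gf_stop("gaitfall_cohort_invalid", "training labels contain one class only")
  if (all(apply(X, 2L, function(col) diff(range(col)) == 0)))
    gf_stop("gaitfall_training_failed", "all feature columns are constant")
  fit <- .mlp_train_cpp(X, y01, cfg$hidden_units, cfg$l2_alpha, cfg$max_epochs,
                        cfg$learning_rate, batch_size = min(200L, nrow(X)),
                        solver = cfg$solver, momentum = 0.9,
                        tol = 1e-4, n_iter_no_change = 10L, seed = cfg$seed)
  structure(list(fit = fit, cfg = cfg, n_features = ncol(X),
                 feature_names = colnames(X)),
            class = "mlp_model")
}

#' @param object an `mlp_model`.
#' @param newdata matrix on the training scale.
#' @param type `"score"` for the continuous faller score in (0, 1) or
#'   `"class"` for the 0.5-threshold label.
#' @rdname train_mlp
#' @export
predict.mlp_model <- function(object, newdata, type = c("score", "class"), ...) {
  type <- match.arg(type)
  s <- as.numeric(.mlp_score_cpp(as.matrix(newdata), object$fit$W1,
                                 object$fit$b1, object$fit$W2, object$fit$b2))
  if (type == "score") s else as.integer(s >= 0.5)
}

#' Stratified fold assignment
#'
#' Shuffles each class with the seeded RNG and deals members round-robin, so
#' per-fold class counts differ from the global proportion by at most one
#' subject and assignment is deterministic given the seed. If the smaller
#' class has fewer members than `n_folds`, the fold count shrinks to that
#' class size with a warning.
#'
#' @param labels factor/character class labels.
#' @param n_folds requested fold count (default 10).
#' @param seed integer seed.
#' @return integer vector of fold ids in `1..n_folds`.
#' @export
stratified_folds <- function(labels, n_folds = 10L, seed = 1L) {
  labels <- as.character(labels)
  cls <- table(labels)
  if (length(cls) < 2L)
    gf_stop("gaitfall_cohort_invalid", "stratified folds need both classes")
  if (min(cls) < n_folds) {
    n_folds <- as.integer(min(cls))
    warning(sprintf("reducing folds to smallest class size (%d)", n_folds))
  }
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in names(cls)) {
      members <- sample(which(labels == cl))
      fold[members] <- rep_len(seq_len(n_folds), length(members))
    }
  })
  fold
}

#' Confusion-matrix metrics
#'
#' @param TP,FN,FP,TN pooled confusion counts; positive class = faller.
#' @return named vector: accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)`,
#'   specificity `TN/(TN+FP)`.
#' @export
compute_metrics <- function(TP, FN, FP, TN) {
  counts <- c(TP, FN, FP, TN)
  if (any(counts < 0) || sum(counts) == 0)
    gf_stop("gaitfall_invalid_input", "confusion counts must be nonnegative with positive total")
  if (TP + FN == 0 || TN + FP == 0)
    gf_stop("gaitfall_undefined_metric", "a class has no evaluated subjects")
  c(accuracy = (TP + TN) / sum(counts),
    sensitivity = TP / (TP + FN),
    specificity = TN / (TN + FP))
}

#' Stratified cross-validation with pooled metrics
#'
#' Per fold: min-max scaling is fit on the training folds only and applied
#' to the held-out fold, the MLP is trained on the training folds, and the
#' held-out subjects are scored. All out-of-fold predictions are pooled into
#' a single confusion matrix (positive class = faller) from which accuracy,
#' sensitivity and specificity are computed; AUC comes from the pooled
#' out-of-fold scores. Per-fold MLP seeds are derived from `seed`.
#'
#' @param X unscaled numeric feature matrix.
#' @param y labels (factor/character, positive class `"faller"`).
#' @param cfg an [mlp_config()].
#' @param n_folds fold count (default 10).
#' @param seed integer seed driving fold assignment and fold-level training
#'   seeds.
#' @param scale fit fold-aware min-max scaling (default TRUE).
#' @return object of class `evaluation_report`: `confusion` (TP, FN, FP,
#'   TN), `accuracy`, `sensitivity`, `specificity`, `AUC`, `folds`,
#'   `scores`, `config`.
#' @export
cross_validate <- function(X, y, cfg = mlp_config(), n_folds = 10L, seed = 1L,
                           scale = TRUE) {
  X <- as.matrix(X)
  y_chr <- as.character(y)
  fold <- stratified_folds(y_chr, n_folds, seed)
  scores <- rep(NA_real_, nrow(X))
  failed <- integer()
  for (k in sort(unique(fold))) {
    tr <- fold != k
    cfg_k <- cfg
    cfg_k$seed <- derive_seed(seed, k)
    Xtr <- X[tr, , drop = FALSE]
    Xte <- X[!tr, , drop = FALSE]
    if (scale) {
      params <- minmax_fit(Xtr)
      Xtr <- minmax_apply(Xtr, params)
      Xte <- minmax_apply(Xte, params)
    }
    model <- tryCatch(train_mlp(Xtr, y_chr[tr], cfg_k),
                      gaitfall_error = function(e) e)
    if (inherits(model, "condition")) { failed <- c(failed, k); next }
    scores[!tr] <- predict(model, Xte, type = "score")
  }
  ok <- !is.na(scores)
  pos <- y_chr == "faller"
  pred <- scores >= 0.5
  TP <- sum(ok & pos & pred); FN <- sum(ok & pos & !pred)
  FP <- sum(ok & !pos & pred); TN <- sum(ok & !pos & !pred)
  metrics <- compute_metrics(TP, FN, FP, TN)
  structure(
    list(confusion = c(TP = TP, FN = FN, FP = FP, TN = TN),
         accuracy = metrics[["accuracy"]],
         sensitivity = metrics[["sensitivity"]],
         specificity = metrics[["specificity"]],
         AUC = auc_scores(scores[ok], pos[ok]),
         folds = fold, failed_folds = failed, scores = scores,
         config = cfg, n_folds = n_folds, seed = seed),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> acc %.3f sens %.3f spec %.3f AUC %.3f (TP %d FN %d FP %d TN %d)\n",
              x$accuracy, x$sensitivity, x$specificity, x$AUC,
              x$confusion[["TP"]], x$confusion[["FN"]],
              x$confusion[["FP"]], x$confusion[["TN"]]))
  invisible(x)
}

#' Build the sweep evaluation function
#'
#' Returns the `eval_fn` used by [selection_sweep()]: for each hidden-layer
#' width it runs [cross_validate()] on the feature subset and emits one grid
#' row. Cell seeds are derived from the global seed and the (K, N, hidden)
#' coordinates, so results do not depend on execution order.
#'
#' @param hidden_range hidden-unit sweep (default `seq(10, 200, by = 10)`).
#' @param n_folds folds for [cross_validate()].
#' @param seed global seed.
#' @param ... passed to [mlp_config()].
#' @return function `(fm_subset, K, N) -> data.frame`.
#' @export
make_eval_fn <- function(hidden_range = seq(10L, 200L, by = 10L),
                         n_folds = 10L, seed = 1L, ...) {
  force(hidden_range); force(n_folds); force(seed)
  function(fm, K, N) {
    do.call(rbind, lapply(hidden_range, function(h) {
      cell_seed <- derive_seed(seed, K * 1000003 + N * 1009 + h)
      rep <- cross_validate(fm$X, fm$labels,
                            mlp_config(hidden_units = h, ...),
                            n_folds = n_folds, seed = cell_seed)
      data.frame(hidden_units = h, AUC = rep$AUC, accuracy = rep$accuracy,
                 sensitivity = rep$sensitivity, specificity = rep$specificity,
                 TP = rep$confusion[["TP"]], FN = rep$confusion[["FN"]],
                 FP = rep$confusion[["FP"]], TN = rep$confusion[["TN"]])
    }))
  }
}

#' Select the best grid configuration
#'
#' Lexicographic rule: maximize accuracy, then sensitivity, then prefer
#' fewer features (smaller N), then fewer hidden units, then smaller K.
#' Deterministic for any grid.
#'
#' @param grid data.frame with columns `K, N, hidden_units, accuracy,
#'   sensitivity` (a [selection_sweep()] `grid`, skipped rows ignored).
#' @return the selected row of the grid (single-row data.frame).
#' @export
model_select <- function(grid) {
  if (inherits(grid, "selection_sweep")) grid <- grid$grid
  if ("skipped" %in% names(grid)) grid <- grid[!grid$skipped, , drop = FALSE]
  if (!nrow(grid))
    gf_stop("gaitfall_invalid_input", "empty evaluation grid")
  ord <- order(-grid$accuracy, -grid$sensitivity, grid$N,
               grid$hidden_units, grid$K)
  grid[ord[1L], , drop = FALSE]
}
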