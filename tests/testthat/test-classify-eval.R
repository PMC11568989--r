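toy_separable <- function(n_per_class = 20, seed = 0) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(2 * n_per_class, 0.25, 0.05), n_per_class),
             matrix(rnorm(2 * n_per_class, 0.75, 0.05), n_per_class))
  colnames(X) <- c("f1", "f2")
  list(X = X, y = rep(c("non_faller", "faller"), each = n_per_class))
}

test_that("stratified folds balance classes and are seed-deterministic", {
  y <- rep(c("faller", "non_faller"), each = 10)
  f <- stratified_folds(y, 10, seed = 4)
  expect_equal(sort(unique(f)), 1:10)
  for (k in 1:10) {
    expect_equal(sum(f == k & y == "faller"), 1L)
    expect_equal(sum(f == k & y == "non_faller"), 1L)
  }
  expect_identical(f, stratified_folds(y, 10, seed = 4))
  expect_false(identical(f, stratified_folds(y, 10, seed = 5)))
  # 73 subjects in 10 folds: sizes differ by at most 1
  y73 <- c(rep("faller", 35), rep("non_faller", 38))
  f73 <- stratified_folds(y73, 10, seed = 1)
  sizes <- tabulate(f73, 10)
  expect_lte(diff(range(sizes)), 2L)  # per-class remainder can stack once
  for (k in 1:10)
    expect_lte(abs(sum(f73 == k & y73 == "faller") - 3.5), 0.5)
  expect_error(stratified_folds(rep("faller", 10), 10, 1),
               class = "gaitfall_cohort_invalid")
  expect_warning(stratified_folds(c(rep("faller", 3), rep("non_faller", 20)), 10, 1),
                 "reducing folds")
})

test_that("pooled confusion metrics match their formulas", {
  m <- compute_metrics(29, 6, 7, 31)
  expect_equal(round(unname(m), 3), c(0.822, 0.829, 0.816))
  expect_equal(unname(compute_metrics(10, 0, 0, 10)), c(1, 1, 1))
  expect_equal(unname(compute_metrics(0, 10, 10, 0)), c(0, 0, 0))
  expect_error(compute_metrics(0, 0, 5, 5), class = "gaitfall_undefined_metric")
  expect_error(compute_metrics(-1, 1, 1, 1), class = "gaitfall_invalid_input")
  # independent recomputation over 1000 random matrices
  set.seed(10)
  for (i in 1:1000) {
    cm <- rpois(4, 8) + c(1, 0, 0, 1)
    m <- compute_metrics(cm[1], cm[2], cm[3], cm[4])
    expect_equal(m[["accuracy"]], (cm[1] + cm[4]) / sum(cm), tolerance = 1e-12)
    expect_equal(m[["sensitivity"]], cm[1] / (cm[1] + cm[2]), tolerance = 1e-12)
    expect_equal(m[["specificity"]], cm[4] / (cm[4] + cm[3]), tolerance = 1e-12)
  }
})

test_that("the MLP separates separable clusters and is seed-deterministic", {
  toy <- toy_separable()
  m <- train_mlp(toy$X, toy$y, mlp_config(hidden_units = 50, seed = 3))
  expect_equal(mean(predict(m, toy$X, type = "class") ==
                      (toy$y == "faller")), 1.0)
  s1 <- predict(train_mlp(toy$X, toy$y, mlp_config(seed = 11)), toy$X)
  s2 <- predict(train_mlp(toy$X, toy$y, mlp_config(seed = 11)), toy$X)
  expect_identical(s1, s2)
  s3 <- predict(train_mlp(toy$X, toy$y, mlp_config(seed = 12)), toy$X)
  expect_false(identical(s1, s3))
  expect_error(train_mlp(toy$X, rep("faller", nrow(toy$X))),
               class = "gaitfall_cohort_invalid")
  expect_error(train_mlp(matrix(1, 10, 2), rep(c("faller", "non_faller"), 5)),
               class = "gaitfall_training_failed")
})

test_that("label-permuted training scores at chance for a fixed config", {
  set.seed(20)
  n <- 40
  X <- matrix(runif(n * 5), n, 5)
  accs <- vapply(1:20, function(s) {
    set.seed(100 + s)
    y <- sample(rep(c("faller", "non_faller"), each = n / 2))
    cross_validate(X, y, mlp_config(hidden_units = 10), n_folds = 5,
                   seed = s)$accuracy
  }, numeric(1))
  # pooled CV accuracy within 3 sigma of 0.5 (binomial sd at n = 40)
  expect_lt(abs(mean(accs) - 0.5), 3 * sqrt(0.25 / 40) / sqrt(20) + 0.05)
  expect_true(all(abs(accs - 0.5) < 3 * sqrt(0.25 / 40) + 0.05))
})

test_that("cross-validation pools out-of-fold predictions into one matrix", {
  toy <- toy_separable(25)
  rep <- cross_validate(toy$X, toy$y, mlp_config(hidden_units = 20),
                        n_folds = 10, seed = 7)
  cm <- rep$confusion
  expect_equal(cm[["TP"]] + cm[["FN"]], 25L)
  expect_equal(cm[["FP"]] + cm[["TN"]], 25L)
  expect_equal(rep$accuracy, (cm[["TP"]] + cm[["TN"]]) / 50, tolerance = 1e-12)
  # strongly separable: pooled metrics and AUC saturate
  expect_equal(rep$accuracy, 1.0)
  expect_equal(rep$AUC, 1.0)
  expect_identical(cross_validate(toy$X, toy$y, mlp_config(hidden_units = 20),
                                  n_folds = 10, seed = 7)$scores, rep$scores)
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(30)
  scores <- runif(60)
  labels <- runif(60) < plogis(4 * (scores - 0.5))
  if (length(unique(labels)) < 2) labels[1:2] <- c(TRUE, FALSE)
  ours <- auc_scores(scores, labels)
  theirs <- as.numeric(pROC::auc(pROC::roc(response = labels,
                                           predictor = scores, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("model selection is lexicographic and reproduces the reference choice", {
  # the six printed configurations of the reference results table
  grid <- data.frame(
    K = c(20, 23, 20, 23, 21, 21),
    N = c(17, 28, 31, 31, 35, 36),
    hidden_units = 50,
    AUC = c(0.863, 0.840, 0.874, 0.881, 0.851, 0.851),
    accuracy = rep(0.822, 6),
    sensitivity = c(0.829, 0.800, 0.771, 0.771, 0.771, 0.800),
    specificity = c(0.816, 0.842, 0.868, 0.868, 0.868, 0.842))
  best <- model_select(grid)
  expect_equal(best$K, 20)
  expect_equal(best$N, 17)
  # single cell returns itself
  expect_equal(model_select(grid[3, ])$N, 31)
  # full tie except K: smaller K wins
  tie <- data.frame(K = c(9, 4), N = 10, hidden_units = 20, AUC = 0.8,
                    accuracy = 0.8, sensitivity = 0.7, specificity = 0.9)
  expect_equal(model_select(tie)$K, 4)
  expect_error(model_select(grid[0, ]), class = "gaitfall_invalid_input")
})
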