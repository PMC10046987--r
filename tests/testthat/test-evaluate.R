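test_that("confusion counts match hand tallies with CAD as positive", {
  cm <- confusion(rep(c(1, 0), each = 4), rep(c(1, 0), each = 4))
  expect_equal(c(cm$TP, cm$TN, cm$FP, cm$FN), c(4, 4, 0, 0))
  cm2 <- confusion(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0), c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0))
  expect_equal(c(cm2$TP, cm2$FN, cm2$FP, cm2$TN), c(3, 1, 1, 5))
  cm3 <- confusion(c(1, 0, 0), c(1, 1, 1)) # all positive predictions
  expect_equal(cm3$TN, 0); expect_equal(cm3$FP, 2)
  expect_error(confusion(c(1, 0), c(1)), class = "iristex_value_error")
})

test_that("metrics match direct formula evaluation, including the derived case", {
  m <- metrics_from_confusion(confusion(rep(c(1, 0), each = 4), rep(c(1, 0), each = 4)))
  expect_equal(as.numeric(m), rep(1, 6))
  cm <- structure(list(TP = 3, FN = 1, FP = 1, TN = 5), class = "confusion_matrix")
  m2 <- metrics_from_confusion(cm)
  expect_equal(unname(m2["accuracy"]), 0.8)
  expect_equal(unname(m2["sensitivity"]), 0.75)
  expect_equal(unname(m2["specificity"]), 5 / 6)
  expect_equal(unname(m2["precision"]), 0.75)
  expect_equal(unname(m2["f1"]), 0.75)
  expect_equal(unname(m2["gmean"]), sqrt(0.75 * 5 / 6))
  # degenerate fold without positives: sensitivity 0, flagged
  cm0 <- structure(list(TP = 0, FN = 0, FP = 1, TN = 4), class = "confusion_matrix")
  m0 <- metrics_from_confusion(cm0)
  expect_equal(unname(m0["sensitivity"]), 0)
  expect_true(attr(m0, "degenerate"))
})

test_that("metrics agree with the formulas on an exhaustive small-count sweep", {
  for (tp in 0:3) for (fn in 0:3) for (fp in 0:3) for (tn in 0:3) {
    if (tp + fn + fp + tn == 0) next
    cm <- structure(list(TP = tp, FN = fn, FP = fp, TN = tn),
                    class = "confusion_matrix")
    m <- metrics_from_confusion(cm)
    sns <- if (tp + fn == 0) 0 else tp / (tp + fn)
    spc <- if (fp + tn == 0) 0 else tn / (fp + tn)
    prc <- if (tp + fp == 0) 0 else tp / (tp + fp)
    expect_equal(unname(m["accuracy"]), (tp + tn) / (tp + fn + fp + tn))
    expect_equal(unname(m["sensitivity"]), sns)
    expect_equal(unname(m["specificity"]), spc)
    expect_equal(unname(m["precision"]), prc)
    expect_equal(unname(m["f1"]), if (prc + sns == 0) 0 else 2 * prc * sns / (prc + sns))
    expect_equal(unname(m["gmean"]), sqrt(sns * spc))
  }
})

test_that("AUC matches the pair-counting oracle exactly on random batteries", {
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.2)), 0.75)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(5, 4, 3, 2)), 1)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(1, 4)), 0.5)
  set.seed(17)
  for (rep in 1:60) {
    n <- sample(4:12, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE)) # both classes guaranteed
    s <- sample(seq(0, 1, by = 0.25), n, replace = TRUE) # many ties
    expect_equal(roc_auc(y, s), auc_oracle(y, s), tolerance = 1e-12)
  }
  expect_error(roc_auc(c(1, 1), c(0.3, 0.4)), class = "iristex_undefined_auc_error")
})

test_that("AUC agrees with the pROC reference on a continuous battery", {
  skip_if_not_installed("pROC")
  set.seed(23)
  y <- sample(0:1, 40, replace = TRUE); y[1:2] <- 0:1
  s <- rnorm(40) + y
  expect_equal(roc_auc(y, s),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<"))),
               tolerance = 1e-12)
})

test_that("the registry holds exactly 22 presets across exactly 5 families", {
  reg <- classifier_registry()
  expect_length(reg, 22)
  fams <- vapply(reg, function(r) r$family, "")
  expect_setequal(unique(fams), c("decision_tree", "naive_bayes", "svm", "knn",
                                  "neural_network"))
  expect_equal(unname(table(fams)[c("decision_tree", "naive_bayes", "svm",
                                    "knn", "neural_network")]),
               c(3L, 2L, 6L, 6L, 5L), ignore_attr = TRUE)
  names_ <- vapply(reg, function(r) r$preset_name, "")
  expect_false(any(duplicated(names_)))
  expect_true("Medium Gaussian SVM" %in% names_)
  expect_true("Linear SVM" %in% names_)
})

test_that("every preset separates an easy table and is reproducible", {
  set.seed(5)
  n <- 60
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(matrix(rnorm(n * 4), n, 4), sig1 = y * 4 + rnorm(n, sd = 0.2),
             sig2 = -3 * y + rnorm(n, sd = 0.2))
  colnames(X) <- paste0("f", 1:6)
  # Coarse KNN (k = 100 on 48 training samples) and Fine Gaussian SVM (tiny
  # kernel scale) are intentionally extreme presets that underfit/overfit small
  # easy tables, exactly as their published behavior suggests; they are held
  # only to a weaker bound here.
  weak <- c("Coarse KNN", "Fine Gaussian SVM")
  for (cfg in classifier_registry()) {
    rep1 <- stratified_kfold_eval(X, y, cfg, seed = 11)
    expect_gte(rep1$metrics[["accuracy"]], if (cfg$preset_name %in% weak) 0.4 else 0.9)
    rep2 <- stratified_kfold_eval(X, y, cfg, seed = 11)
    expect_identical(rep1$metrics, rep2$metrics)
    expect_equal(rep1$n_folds, 5)
    expect_equal(nrow(rep1$per_fold), 5)
  }
})

test_that("label-free noise scores near chance for a representative preset", {
  set.seed(31)
  n <- 80
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * 10), n, 10)
  colnames(X) <- paste0("f", 1:10)
  cfg <- classifier_registry()[[6]] # Linear SVM
  rep1 <- stratified_kfold_eval(X, y, cfg, seed = 2)
  band <- 1.96 * sqrt(0.25 / n)
  expect_lt(abs(rep1$metrics[["accuracy"]] - 0.5), band + 0.08)
})

test_that("stratification keeps the class ratio and rejects tiny classes", {
  y <- rep(c(0L, 1L), c(40, 10))
  f <- iristex:::stratified_folds(y, 5, seed = 1)
  for (k in 1:5) {
    expect_equal(sum(y[f == k] == 1), 2)
    expect_equal(sum(y[f == k] == 0), 8)
  }
  expect_error(iristex:::stratified_folds(rep(c(0L, 1L), c(46, 4)), 5, 1),
               class = "iristex_stratification_error")
})
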