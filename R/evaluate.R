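#' Binary confusion matrix with CAD (label 1) as the positive class
#'
#' @param y_true,y_pred equal-length 0/1 vectors.
#' @return Object of class `"confusion_matrix"`: list with counts `TP`, `FN`,
#'   `FP`, `TN`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    iristex_error("y_true and y_pred must have equal length", "iristex_value_error")
  }
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  structure(list(
    TP = sum(y_true == 1 & y_pred == 1),
    FN = sum(y_true == 1 & y_pred == 0),
    FP = sum(y_true == 0 & y_pred == 1),
    TN = sum(y_true == 0 & y_pred == 0)
  ), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion (positive = CAD): TP=%d FN=%d FP=%d TN=%d\n",
              x$TP, x$FN, x$FP, x$TN))
  invisible(x)
}

#' Confusion-matrix metrics
#'
#' Sensitivity TP/(TP+FN), specificity TN/(FP+TN), precision TP/(TP+FP),
#' accuracy (TP+TN)/total, F1 = 2*PRC*SNS/(PRC+SNS) and the geometric mean
#' sqrt(SNS*SPC). Any 0/0 denominator yields 0 and sets the `"degenerate"`
#' attribute.
#'
#' @param cm a [confusion()] result.
#' @return Named numeric vector
#'   `(accuracy, sensitivity, specificity, precision, f1, gmean)`.
#' @export
metrics_from_confusion <- function(cm) {
  total <- cm$TP + cm$FN + cm$FP + cm$TN
  if (total == 0) iristex_error("empty confusion matrix", "iristex_value_error")
  safe <- function(num, den) if (den == 0) 0 else num / den
  degenerate <- (cm$TP + cm$FN == 0) || (cm$FP + cm$TN == 0) || (cm$TP + cm$FP == 0)
  sns <- safe(cm$TP, cm$TP + cm$FN)
  spc <- safe(cm$TN, cm$FP + cm$TN)
  prc <- safe(cm$TP, cm$TP + cm$FP)
  f1 <- safe(2 * prc * sns, prc + sns)
  out <- c(accuracy = (cm$TP + cm$TN) / total, sensitivity = sns,
           specificity = spc, precision = prc, f1 = f1,
           gmean = sqrt(sns * spc))
  attr(out, "degenerate") <- degenerate
  out
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the (FPR, TPR) curve swept over score thresholds,
#' computed as the equivalent rank statistic: the probability that a random
#' positive outscores a random negative, with ties counted 1/2.
#'
#' @param y_true 0/1 labels (both classes present).
#' @param scores continuous scores, larger = more positive.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  n1 <- sum(y_true == 1); n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) {
    iristex_error("AUC undefined with a single class", "iristex_undefined_auc_error")
  }
  r <- rank(scores) # ties get midranks, which implements the 1/2 convention
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified fold assignment: within each class, samples are shuffled and dealt
# round-robin, preserving the class ratio within +-1 sample per fold.
stratified_folds <- function(y, n_folds, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      if (length(idx) < n_folds) {
        iristex_error("each class needs at least n_folds samples",
                      "iristex_stratification_error")
      }
      fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

#' Stratified k-fold cross-validated evaluation of one classifier preset
#'
#' Splits the samples into stratified folds, fits on the training folds
#' (z-scoring the inputs inside the training fold when the preset requires it),
#' predicts the held-out fold, and computes the confusion-matrix metric suite
#' plus AUC from the continuous scores. Reported values are arithmetic means
#' over folds. Deterministic given `seed`.
#'
#' @param X numeric matrix, samples x features.
#' @param y 0/1 labels (each class needs >= `n_folds` samples).
#' @param config a `"classifier_config"` from [classifier_registry()].
#' @param n_folds folds (default 5).
#' @param seed integer seed for fold assignment and classifier initialization.
#' @return Object of class `"metrics_report"`: list with `preset_name`,
#'   `metrics` (named mean vector incl. `auc`), `per_fold` (data frame) and
#'   `n_folds`.
#' @export
stratified_kfold_eval <- function(X, y, config, n_folds = 5L, seed = 1L) {
  X <- as.matrix(X); y <- as.integer(y)
  fold <- stratified_folds(y, n_folds, seed)
  per <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    tr <- fold != f; te <- !tr
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    if (isTRUE(config$standardize_inputs)) {
      mu <- colMeans(Xtr)
      sdv <- apply(Xtr, 2, stats::sd); sdv[sdv == 0] <- 1
      Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
      Xte <- sweep(sweep(Xte, 2, mu), 2, sdv, "/")
    }
    fitted <- fit_classifier(config, Xtr, y[tr], seed = seed + f)
    pred <- predict_classifier(fitted, Xte)
    m <- metrics_from_confusion(confusion(y[te], pred$class))
    auc <- roc_auc(y[te], pred$score)
    per[[f]] <- c(fold = f, m, auc = auc)
  }
  per <- as.data.frame(do.call(rbind, per))
  metrics <- colMeans(per[, -1, drop = FALSE])
  structure(list(preset_name = config$preset_name, metrics = metrics,
                 per_fold = per, n_folds = n_folds),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("%s (%d-fold CV means):\n", x$preset_name, x$n_folds))
  print(round(x$metrics, 4))
  invisible(x)
}

#' Evaluate many classifier presets on one feature table
#'
#' @param X numeric matrix, samples x features.
#' @param y 0/1 labels.
#' @param configs list of presets (default: the full [classifier_registry()]).
#' @param n_folds,seed passed to [stratified_kfold_eval()].
#' @return Data frame with one row per preset: family, preset and the mean CV
#'   metrics.
#' @export
evaluate_registry <- function(X, y, configs = classifier_registry(),
                              n_folds = 5L, seed = 1L) {
  rows <- lapply(configs, function(cfg) {
    rep <- stratified_kfold_eval(X, y, cfg, n_folds = n_folds, seed = seed)
    data.frame(family = cfg$family, preset = cfg$preset_name,
               t(rep$metrics), check.names = FALSE)
  })
  do.call(rbind, rows)
}
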