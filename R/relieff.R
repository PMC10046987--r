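#' ReliefF feature ranking
#'
#' Two-class ReliefF (Kononenko's k-nearest-neighbor form): every sample is
#' used in turn (m = n); its k nearest hits (same class) and k nearest misses
#' (other class) are found under Manhattan distance on min-max scaled features;
#' each feature weight accumulates the miss differences minus the hit
#' differences, normalized by `m * k`. With scaled features the weights lie in
#' \[-1, 1\]. Neighbor ties are broken by ascending sample index, so the
#' ranking is deterministic; `seed` is accepted for interface stability but
#' never influences the result.
#'
#' @param X numeric matrix, samples x features (no missing values).
#' @param y binary labels (0/1), both classes present.
#' @param k_neighbors neighbors per class (each class must have at least
#'   `k_neighbors + 1` samples).
#' @param seed unused tie-break seed (ties resolve by index first).
#' @return An object of class `"relieff_ranking"`: list with `weights`
#'   (named per feature) and `order` (feature indices by descending weight,
#'   ties by ascending index).
#' @export
relieff_rank <- function(X, y, k_neighbors = 10L, seed = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2) {
    iristex_error("ReliefF needs both classes present", "iristex_single_class_error")
  }
  if (anyNA(X)) iristex_error("missing values in feature table", "iristex_value_error")
  k <- as.integer(k_neighbors)
  if (min(table(y)) < k + 1) {
    iristex_error("each class needs at least k_neighbors + 1 samples",
                  "iristex_value_error")
  }
  n <- nrow(X); p <- ncol(X)
  # min-max scale; constant features contribute 0 everywhere
  rng <- apply(X, 2, function(v) diff(range(v)))
  mins <- apply(X, 2, min)
  S <- sweep(X, 2, mins)
  nz <- rng > 0
  S[, nz] <- sweep(S[, nz, drop = FALSE], 2, rng[nz], "/")
  S[, !nz] <- 0

  D <- as.matrix(stats::dist(S, method = "manhattan"))
  w <- numeric(p)
  for (m in seq_len(n)) {
    same <- which(y == y[m]); same <- same[same != m]
    other <- which(y != y[m])
    hits <- same[order(D[m, same], same)][seq_len(k)]
    misses <- other[order(D[m, other], other)][seq_len(k)]
    dh <- abs(sweep(S[hits, , drop = FALSE], 2, S[m, ]))
    dm <- abs(sweep(S[misses, , drop = FALSE], 2, S[m, ]))
    w <- w + colSums(dm) - colSums(dh)
  }
  w <- w / (n * k)
  names(w) <- colnames(X)
  structure(list(weights = w, order = order(-w, seq_len(p))),
            class = "relieff_ranking")
}

#' @export
print.relieff_ranking <- function(x, ...) {
  cat(sprintf("ReliefF ranking of %d features; top 5:\n", length(x$weights)))
  top <- x$order[seq_len(min(5, length(x$order)))]
  nm <- names(x$weights); if (is.null(nm)) nm <- paste0("f", seq_along(x$weights))
  for (i in top) cat(sprintf("  %-40s %+0.4f\n", nm[i], x$weights[i]))
  invisible(x)
}

#' Select the top-k features of a ranking
#'
#' @param ranking a [relieff_rank()] result.
#' @param k number of features (1 <= k <= n_features).
#' @return Integer vector: the first `k` indices of the ranking order. Top-k
#'   lists are prefix-consistent: `select_top(r, k1)` is a prefix of
#'   `select_top(r, k2)` whenever `k1 < k2`.
#' @export
select_top <- function(ranking, k) {
  n <- length(ranking$order)
  if (k < 1 || k > n) {
    iristex_error(sprintf("k must be in 1..%d", n), "iristex_value_error")
  }
  ranking$order[seq_len(k)]
}

#' Point-biserial correlation of each feature with the class label
#'
#' Pearson correlation between each feature column and the 0/1 label. Constant
#' features yield 0 and are flagged in the `"constant"` attribute.
#'
#' @param X numeric matrix, samples x features.
#' @param y binary labels (must not be constant).
#' @return Numeric vector of per-feature correlations.
#' @export
pointwise_correlation <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (stats::var(y) == 0) {
    iristex_error("label vector is constant", "iristex_value_error")
  }
  const <- apply(X, 2, function(v) stats::var(v) == 0)
  r <- rep(0, ncol(X))
  r[!const] <- as.vector(stats::cor(X[, !const, drop = FALSE], y))
  names(r) <- colnames(X)
  attr(r, "constant") <- const
  if (any(const)) {
    warning(sprintf("%d constant feature(s) assigned correlation 0", sum(const)))
  }
  r
}
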