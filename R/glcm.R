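#' Quantize a matrix to L gray levels
#'
#' Uniform min-max binning into levels `0 .. L-1`: needed because wavelet
#' detail coefficients are signed and unbounded. A constant input maps to
#' level 0.
#'
#' @param band numeric matrix.
#' @param L number of levels (>= 2).
#' @return Integer matrix with values in `0 .. L-1` and attribute `L`.
#' @export
quantize <- function(band, L) {
  if (L < 2) iristex_error("L must be >= 2", "iristex_value_error")
  mn <- min(band); mx <- max(band)
  q <- if (mx == mn) {
    matrix(0L, nrow(band), ncol(band))
  } else {
    matrix(pmin(as.integer(floor((band - mn) / (mx - mn) * L)), L - 1L),
           nrow(band), ncol(band))
  }
  attr(q, "L") <- as.integer(L)
  q
}

# Row/column offsets of the four standard directions (dr, dc), in matrix
# coordinates. 0 deg = rightwards along a row; angles grow counter-clockwise in
# conventional image-axes terms, i.e. 45 deg pairs a pixel with its upper-right
# neighbor.
direction_offset <- function(theta, d = 1L) {
  switch(as.character(theta),
    "0" = c(0L, d), "45" = c(-d, d), "90" = c(-d, 0L), "135" = c(-d, -d),
    iristex_error("theta must be one of 0, 45, 90, 135", "iristex_value_error")
  )
}

#' Gray-level co-occurrence matrix
#'
#' Counts pairs of levels at pixel offset `d` in direction `theta`, optionally
#' symmetrized by adding the transposed counts (each unordered pair counted in
#' both orders), then normalized to probabilities.
#'
#' @param q a [quantize()]d image (or integer matrix with levels `0 .. L-1`;
#'   supply `L` via attribute).
#' @param theta direction in degrees: 0, 45, 90 or 135.
#' @param d neighbor distance in pixels.
#' @param symmetric add the transpose before normalizing (default `TRUE`).
#' @return `L x L` matrix of probabilities summing to 1, class `"glc_matrix"`,
#'   with attributes `d` and `theta`.
#' @export
glcm <- function(q, theta, d = 1L, symmetric = TRUE) {
  L <- attr(q, "L")
  if (is.null(L)) L <- max(q) + 1L
  off <- direction_offset(theta, d)
  nr <- nrow(q); nc <- ncol(q)
  rows <- seq_len(nr); cols <- seq_len(nc)
  r1 <- rows[rows + off[1] >= 1 & rows + off[1] <= nr]
  c1 <- cols[cols + off[2] >= 1 & cols + off[2] <= nc]
  if (length(r1) == 0 || length(c1) == 0) {
    iristex_error("image smaller than the co-occurrence offset",
                  "iristex_empty_glcm_error")
  }
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + off[1], c1 + off[2], drop = FALSE]
  counts <- matrix(tabulate(as.vector(a) * L + as.vector(b) + 1L, nbins = L * L),
                   L, L, byrow = TRUE)
  if (symmetric) counts <- counts + t(counts)
  P <- counts / sum(counts)
  structure(P, class = c("glc_matrix", "matrix"), d = d, theta = theta)
}

#' Names of the 22 co-occurrence features, in output order
#' @return Character vector of length 22.
#' @export
glcm_feature_names <- function() {
  c("autocorrelation", "cluster_prominence", "cluster_shade", "contrast",
    "correlation", "difference_entropy", "difference_variance", "dissimilarity",
    "energy", "entropy", "homogeneity", "imc1", "imc2",
    "inverse_difference_moment", "maximum_probability", "sum_average",
    "sum_entropy", "sum_of_squares", "sum_variance",
    "maximal_correlation_coefficient", "inverse_difference_normalized",
    "inverse_difference_moment_normalized")
}

#' Haralick-type features of a co-occurrence matrix
#'
#' The 22 classical co-occurrence statistics, computed with 1-based level
#' indices `i, j = 1..L`, logarithms base 2 and the `0 * log 0 := 0`
#' convention. `correlation` is defined as 0 (and flagged via the
#' `"degenerate"` attribute) when a marginal standard deviation vanishes. The
#' maximal correlation coefficient is `sqrt` of the second-largest eigenvalue
#' of Haralick's Q matrix (zero-marginal levels dropped first), clipped to
#' \[0, 1\]; set `mcc_sqrt = FALSE` for the raw eigenvalue.
#'
#' @param P a [glcm()] result (entries must sum to 1).
#' @param mcc_sqrt take the square root of the second eigenvalue (default).
#' @return Named numeric vector of length 22, in [glcm_feature_names()] order.
#' @export
glcm_features <- function(P, mcc_sqrt = TRUE) {
  L <- nrow(P)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mu_x <- sum(seq_len(L) * px); mu_y <- sum(seq_len(L) * py)
  sd_x <- sqrt(sum((seq_len(L) - mu_x)^2 * px))
  sd_y <- sqrt(sum((seq_len(L) - mu_y)^2 * py))
  mu <- (mu_x + mu_y) / 2

  # sum / difference distributions
  k_sum <- 2:(2 * L)
  p_sum <- vapply(k_sum, function(k) sum(P[i + j == k]), 0)
  k_dif <- 0:(L - 1)
  p_dif <- vapply(k_dif, function(k) sum(P[abs(i - j) == k]), 0)

  log2z <- function(v) ifelse(v > 0, log2(v), 0)
  ent <- function(p) -sum(p * log2z(p))

  HX <- ent(px); HY <- ent(py); HXY <- ent(as.vector(P))
  pxpy <- outer(px, py)
  HXY1 <- -sum(P * log2z(pxpy))
  HXY2 <- -sum(pxpy * log2z(pxpy))

  degenerate <- sd_x == 0 || sd_y == 0
  correlation <- if (degenerate) 0 else
    (sum(i * j * P) - mu_x * mu_y) / (sd_x * sd_y)

  mu_dif <- sum(k_dif * p_dif)
  mu_sum <- sum(k_sum * p_sum)

  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (HXY2 - HXY))))

  # maximal correlation coefficient
  keep <- px > 0 & py > 0
  mcc <- 0
  if (sum(keep) >= 2) {
    Pk <- P[keep, keep, drop = FALSE]
    pxk <- px[keep]; pyk <- py[keep]
    Q <- (Pk / pxk) %*% t(Pk / matrix(pyk, nrow(Pk), ncol(Pk), byrow = TRUE))
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    l2 <- min(max(ev[2], 0), 1)
    mcc <- if (mcc_sqrt) sqrt(l2) else l2
  }

  out <- c(
    autocorrelation = sum(i * j * P),
    cluster_prominence = sum((i + j - 2 * mu)^4 * P),
    cluster_shade = sum((i + j - 2 * mu)^3 * P),
    contrast = sum((i - j)^2 * P),
    correlation = correlation,
    difference_entropy = ent(p_dif),
    difference_variance = sum((k_dif - mu_dif)^2 * p_dif),
    dissimilarity = sum(abs(i - j) * P),
    energy = sum(P^2),
    entropy = HXY,
    homogeneity = sum(P / (1 + (i - j)^2)),
    imc1 = imc1,
    imc2 = imc2,
    inverse_difference_moment = sum(P / (1 + abs(i - j))),
    maximum_probability = max(P),
    sum_average = mu_sum,
    sum_entropy = ent(p_sum),
    sum_of_squares = sum((i - mu_x)^2 * P),
    sum_variance = sum((k_sum - mu_sum)^2 * p_sum),
    maximal_correlation_coefficient = mcc,
    inverse_difference_normalized = sum(P / (1 + abs(i - j) / L)),
    inverse_difference_moment_normalized = sum(P / (1 + (i - j)^2 / L^2))
  )
  attr(out, "degenerate") <- degenerate
  out
}
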