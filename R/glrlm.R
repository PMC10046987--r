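#' Gray-level run-length matrix
#'
#' A run is a maximal linear array of adjacent pixels with the same level along
#' direction `theta`. Entry `R[i, j]` counts the runs of level `i - 1` (levels
#' are 0-based in the quantized image) with length `j`. Scan lines are rows
#' (0 deg), columns (90 deg), up-right diagonals (45 deg) and up-left diagonals
#' (135 deg); every pixel belongs to exactly one run per direction.
#'
#' @param q a [quantize()]d image.
#' @param theta direction in degrees: 0, 45, 90 or 135.
#' @return `L x max(dim(q))` integer matrix of run counts, class
#'   `"glrl_matrix"`, with attributes `n_pixels` and `theta`.
#' @export
glrlm <- function(q, theta) {
  L <- attr(q, "L")
  if (is.null(L)) L <- max(q) + 1L
  nr <- nrow(q); nc <- ncol(q)
  lines <- switch(as.character(theta),
    "0" = lapply(seq_len(nr), function(r) q[r, ]),
    "90" = lapply(seq_len(nc), function(c) q[, c]),
    # 45 deg: up-right neighbors (r-1, c+1) share a line <=> constant r + c
    "45" = split(as.vector(q), row(q) + col(q)),
    # 135 deg: up-left neighbors (r-1, c-1) share a line <=> constant r - c
    "135" = split(as.vector(q), row(q) - col(q)),
    iristex_error("theta must be one of 0, 45, 90, 135", "iristex_value_error")
  )
  rmax <- max(nr, nc)
  R <- matrix(0L, L, rmax)
  for (v in lines) {
    runs <- rle(as.vector(v))
    idx <- cbind(runs$values + 1L, runs$lengths)
    for (k in seq_len(nrow(idx))) R[idx[k, 1], idx[k, 2]] <- R[idx[k, 1], idx[k, 2]] + 1L
  }
  structure(R, class = c("glrl_matrix", "matrix"),
            n_pixels = nr * nc, theta = theta)
}

#' Names of the 7 run-length features, in output order
#' @return Character vector of length 7.
#' @export
glrlm_feature_names <- function() {
  c("sre", "lre", "gln", "rp", "rln", "lgre", "hgre")
}

#' Run-length features
#'
#' The seven classical run-length statistics: short-run emphasis, long-run
#' emphasis, gray-level non-uniformity, run percentage (number of runs divided
#' by the number of pixels), run-length non-uniformity, and low/high gray-level
#' run emphasis. Gray-level indices `i` are 1-based in the LGRE/HGRE weights.
#'
#' @param R a [glrlm()] result.
#' @return Named numeric vector of length 7, in [glrlm_feature_names()] order.
#' @export
glrlm_features <- function(R) {
  n_runs <- sum(R)
  if (n_runs == 0) iristex_error("empty run-length matrix", "iristex_empty_glrlm_error")
  np <- attr(R, "n_pixels")
  if (is.null(np)) np <- sum(t(t(unclass(R)) * seq_len(ncol(R))))
  G <- nrow(R); J <- ncol(R)
  i <- matrix(seq_len(G), G, J)
  j <- matrix(seq_len(J), G, J, byrow = TRUE)
  Rm <- unclass(R)
  c(
    sre = sum(Rm / j^2) / n_runs,
    lre = sum(Rm * j^2) / n_runs,
    gln = sum(rowSums(Rm)^2) / n_runs,
    rp = n_runs / np,
    rln = sum(colSums(Rm)^2) / n_runs,
    lgre = sum(Rm / i^2) / n_runs,
    hgre = sum(Rm * i^2) / n_runs
  )
}
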