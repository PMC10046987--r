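# Orthogonal filter banks. Periodized convolution keeps the transform exactly
# orthogonal on even-length signals, which the reconstruction and
# energy-conservation tests rely on.
wavelet_filters <- function(name) {
  lo <- switch(name,
    haar = c(1, 1) / sqrt(2),
    db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
    iristex_error(sprintf("unknown wavelet '%s' (available: haar, db2)", name),
                  "iristex_config_error")
  )
  L <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(L) - 1) # quadrature mirror filter
  list(lo = lo, hi = hi)
}

# One-level periodized analysis of the columns of x (treats each column as a
# signal); returns list(a, d) with ceiling(n/2) rows each. Odd lengths are
# edge-padded by one sample first.
dwt_cols <- function(x, lo, hi) {
  n <- nrow(x)
  if (n %% 2 == 1) {
    x <- rbind(x, x[n, , drop = FALSE])
    n <- n + 1
  }
  L <- length(lo)
  nh <- n %/% 2
  idx <- outer(seq(1, n, by = 2), 0:(L - 1), `+`) # start at sample 2k-1
  idx <- ((idx - 1) %% n) + 1
  a <- matrix(0, nh, ncol(x)); d <- matrix(0, nh, ncol(x))
  for (m in seq_len(L)) {
    a <- a + lo[m] * x[idx[, m], , drop = FALSE]
    d <- d + hi[m] * x[idx[, m], , drop = FALSE]
  }
  list(a = a, d = d)
}

# Inverse of dwt_cols for even original length (periodized synthesis).
idwt_cols <- function(a, d, lo, hi) {
  n <- 2 * nrow(a)
  L <- length(lo)
  x <- matrix(0, n, ncol(a))
  starts <- seq(1, n, by = 2)
  for (m in seq_len(L)) {
    pos <- ((starts + m - 2) %% n) + 1
    x[pos, ] <- x[pos, ] + lo[m] * a + hi[m] * d
  }
  x
}

#' One-level 2-D discrete wavelet transform
#'
#' Separable single-level decomposition of a gray-level matrix into four
#' sub-bands: `cA` (approximation, LL), `cH` (horizontal detail: low-pass along
#' the rows' direction, high-pass across rows - responds to horizontal edges),
#' `cV` (vertical detail) and `cD` (diagonal detail). Filters are periodized
#' orthogonal banks (Haar by default), so the transform conserves energy and
#' reconstructs perfectly; odd dimensions are edge-padded by one sample.
#'
#' @param x numeric matrix (at least 2x2).
#' @param wavelet `"haar"` (default) or `"db2"`.
#' @return An object of class `"subbands"`: list with matrices `cA`, `cH`,
#'   `cV`, `cD`, each `ceiling(nrow/2) x ceiling(ncol/2)`, and the wavelet name.
#' @export
dwt2_level1 <- function(x, wavelet = "haar") {
  if (!is.matrix(x) || nrow(x) < 2 || ncol(x) < 2) {
    iristex_error("input must be a matrix of at least 2x2", "iristex_value_error")
  }
  f <- wavelet_filters(wavelet)
  # filter along x (columns of the image = rows of t(x))
  row_pass <- dwt_cols(t(x), f$lo, f$hi)
  Lx <- t(row_pass$a); Hx <- t(row_pass$d)
  # then along y (rows)
  ll <- dwt_cols(Lx, f$lo, f$hi)
  hl <- dwt_cols(Hx, f$lo, f$hi)
  structure(list(cA = ll$a, cH = ll$d, cV = hl$a, cD = hl$d, wavelet = wavelet),
            class = "subbands")
}

#' Inverse one-level 2-D wavelet transform
#'
#' Reconstructs the input of [dwt2_level1()] (exactly, for even input
#' dimensions and an orthogonal filter bank).
#'
#' @param bands a `"subbands"` object.
#' @return Numeric matrix of size `2*nrow(cA) x 2*ncol(cA)`.
#' @export
idwt2_level1 <- function(bands) {
  f <- wavelet_filters(bands$wavelet)
  Lx <- idwt_cols(bands$cA, bands$cH, f$lo, f$hi)
  Hx <- idwt_cols(bands$cV, bands$cD, f$lo, f$hi)
  t(idwt_cols(t(Lx), t(Hx), f$lo, f$hi))
}

#' @export
print.subbands <- function(x, ...) {
  cat(sprintf("one-level 2-D DWT (%s): four %d x %d sub-bands (cA, cH, cV, cD)\n",
              x$wavelet, nrow(x$cA), ncol(x$cA)))
  invisible(x)
}
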