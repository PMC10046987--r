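#' First-order statistics of a sub-band
#'
#' Mean, standard deviation (1/(N-1) form), histogram entropy (base 2, over a
#' 256-bin min-max histogram), skewness and kurtosis (population moment
#' ratios). Degenerate (constant) input yields std 0, entropy 0, skewness 0 and
#' kurtosis 0 by convention.
#'
#' @param band non-empty numeric matrix or vector.
#' @param entropy_bins histogram bins for the entropy estimate.
#' @return Named numeric vector `(mean, std, entropy, skewness, kurtosis)`.
#' @export
first_order_stats <- function(band, entropy_bins = 256L) {
  x <- as.numeric(band)
  n <- length(x)
  if (n == 0) iristex_error("empty band", "iristex_value_error")
  m <- mean(x)
  if (n == 1 || max(x) == min(x)) {
    return(c(mean = m, std = 0, entropy = 0, skewness = 0, kurtosis = 0))
  }
  s <- stats::sd(x)
  p <- tabulate(as.vector(quantize(matrix(x, 1), entropy_bins)) + 1L,
                nbins = entropy_bins) / n
  entropy <- -sum(p[p > 0] * log2(p[p > 0]))
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  c(mean = m, std = s, entropy = entropy,
    skewness = m3 / m2^1.5, kurtosis = m4 / m2^2)
}

#' Average feature vectors over the four directions
#'
#' @param per_theta list of four equal-length numeric vectors, one per
#'   direction (0, 45, 90, 135 degrees).
#' @return The element-wise arithmetic mean.
#' @export
directional_average <- function(per_theta) {
  if (length(per_theta) != 4 || any(vapply(per_theta, is.null, TRUE))) {
    iristex_error("need feature values for all four directions",
                  "iristex_value_error")
  }
  rowMeans(do.call(cbind, per_theta))
}

glcm_directions <- c(0, 45, 90, 135)

#' Names of the 136 texture features, in vector order
#'
#' For each sub-band in the order `cA, cH, cV, cD`: the 5 first-order
#' statistics, the 22 co-occurrence features, the 7 run-length features; names
#' are `"<band>_<feature>"`.
#'
#' @return Character vector of length 136.
#' @export
feature_names <- function() {
  per_band <- c(c("mean", "std", "entropy", "skewness", "kurtosis"),
                glcm_feature_names(), glrlm_feature_names())
  as.vector(vapply(c("cA", "cH", "cV", "cD"),
                   function(b) paste(b, per_band, sep = "_"),
                   character(34)))
}

#' Extract the 136-value texture descriptor of a ROI
#'
#' Decomposes the ROI with a one-level 2-D wavelet transform and, for each of
#' the four sub-bands, computes 5 first-order statistics, the direction-averaged
#' 22 co-occurrence features (8 quantization levels, distance 1, directions 0,
#' 45, 90, 135 degrees) and the direction-averaged 7 run-length features
#' (16 quantization levels). Deterministic: the same ROI always yields a
#' bit-identical vector.
#'
#' @param roi gray-level matrix (the 190 x 120 heart ROI by default pipeline).
#' @param wavelet wavelet name for [dwt2_level1()].
#' @param glcm_levels,glrlm_levels quantization levels of the two texture
#'   matrices.
#' @param d co-occurrence neighbor distance.
#' @return Named numeric vector of length 136 (names = [feature_names()]).
#' @export
extract_feature_vector <- function(roi, wavelet = "haar", glcm_levels = 8L,
                                   glrlm_levels = 16L, d = 1L) {
  bands <- dwt2_level1(as_gray_matrix(roi), wavelet)
  out <- unlist(lapply(c("cA", "cH", "cV", "cD"), function(b) {
    band <- bands[[b]]
    stats5 <- first_order_stats(band)
    q8 <- quantize(band, glcm_levels)
    glcm22 <- directional_average(lapply(glcm_directions, function(th) {
      glcm_features(glcm(q8, th, d = d))
    }))
    q16 <- quantize(band, glrlm_levels)
    glrlm7 <- directional_average(lapply(glcm_directions, function(th) {
      glrlm_features(glrlm(q16, th))
    }))
    c(stats5, glcm22, glrlm7)
  }))
  names(out) <- feature_names()
  out
}
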