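#' Search configuration for the integro-differential operator
#'
#' Controls the circle search: candidate radius range, grid strides, the
#' Gaussian blur applied to the radial derivative profile, the angular sampling
#' density of the contour integral, and optional arc masking (angular intervals
#' excluded from the integral, e.g. eyelid-covered arcs).
#'
#' @param radius_min,radius_max candidate radius range, pixels.
#' @param center_stride,radius_stride grid steps, pixels (>= 1).
#' @param sigma std of the Gaussian smoothing of the radial derivative, in
#'   radius steps.
#' @param n_angular_samples samples of the contour integral (>= 64).
#' @param arc_mask `NULL`, or a list of `c(start, end)` clock-angle intervals in
#'   degrees to exclude (0 = 12 o'clock, clockwise).
#' @param response_floor minimum acceptable operator response (gray-levels per
#'   radius step); below it the search reports no circle.
#' @param coarse_factor integer downscaling factor of the coarse search pass.
#' @param dark_quantile dark-center prior of the coarse pupil pass: candidate
#'   centers are restricted to pixels at or below this intensity quantile (the
#'   pupil is the darkest structure of an eye image). Set to 1 to disable;
#'   ignored by the exhaustive method and by center-constrained searches.
#' @return An object of class `"search_config"`.
#' @export
search_config <- function(radius_min, radius_max, center_stride = 1L,
                          radius_stride = 1L, sigma = 1, n_angular_samples = 128L,
                          arc_mask = NULL, response_floor = 1.5,
                          coarse_factor = 4L, dark_quantile = 0.08) {
  if (!(radius_min > 0 && radius_min < radius_max)) {
    iristex_error("need 0 < radius_min < radius_max", "iristex_config_error")
  }
  if (center_stride < 1 || radius_stride < 1) {
    iristex_error("strides must be >= 1", "iristex_config_error")
  }
  if (n_angular_samples < 64) {
    iristex_error("n_angular_samples must be >= 64", "iristex_config_error")
  }
  structure(list(radius_min = radius_min, radius_max = radius_max,
                 center_stride = as.integer(center_stride),
                 radius_stride = as.integer(radius_stride),
                 sigma = sigma, n_angular_samples = as.integer(n_angular_samples),
                 arc_mask = arc_mask, response_floor = response_floor,
                 coarse_factor = as.integer(coarse_factor),
                 dark_quantile = dark_quantile),
            class = "search_config")
}

# Angles (radians, clock convention) of the contour samples after arc masking.
contour_angles <- function(n, arc_mask = NULL) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  if (!is.null(arc_mask)) {
    deg <- th * 180 / pi
    keep <- rep(TRUE, n)
    for (iv in arc_mask) {
      a <- iv[1] %% 360; b <- iv[2] %% 360
      keep <- keep & if (a <= b) !(deg >= a & deg < b) else !(deg >= a | deg < b)
    }
    th <- th[keep]
    if (length(th) == 0) {
      iristex_error("arc mask excludes every contour sample", "iristex_config_error")
    }
  }
  th
}

#' Mean intensity along a circular arc
#'
#' Arithmetic mean of bilinearly interpolated intensities at `n_angular_samples`
#' equally spaced angles on the circle, skipping masked arcs. This is the
#' normalized contour integral of the integro-differential operator.
#'
#' @param image grayscale matrix.
#' @param circ an [circle()].
#' @param n_angular_samples number of contour samples.
#' @param arc_mask see [search_config()].
#' @return Mean gray-level along the unmasked arc.
#' @export
circular_mean_intensity <- function(image, circ, n_angular_samples = 128L,
                                    arc_mask = NULL) {
  image <- as_gray_matrix(image)
  if (!circle_in_image(circ, nrow(image), ncol(image))) {
    iristex_error("circle exits the image", "iristex_out_of_bounds_error")
  }
  th <- contour_angles(n_angular_samples, arc_mask)
  d <- clock_dir(th)
  mean(bilinear_interp(image, circ$x0 + circ$r * d$dx, circ$y0 + circ$r * d$dy))
}

# Vectorized circular means for one center and many radii: samples all
# radii x angles in one interpolation call. Radii whose circle exits the image
# yield NA.
circular_means_multi <- function(image, x0, y0, radii, th) {
  nr <- nrow(image); nc <- ncol(image)
  d <- clock_dir(th)
  xs <- outer(radii, d$dx) + x0
  ys <- outer(radii, d$dy) + y0
  vals <- bilinear_interp(image, as.vector(xs), as.vector(ys))
  m <- rowMeans(matrix(vals, nrow = length(radii)))
  bad <- x0 - radii < 1 | x0 + radii > nc | y0 - radii < 1 | y0 + radii > nr
  m[bad] <- NA_real_
  m
}

# Discrete Gaussian kernel (std in samples), half-width 3*sigma, normalized.
gauss_kernel <- function(sigma) {
  hw <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-hw):hw)^2 / (2 * sigma^2))
  k / sum(k)
}

# Convolve with edge replication.
conv_replicate <- function(v, k) {
  hw <- (length(k) - 1L) %/% 2L
  vp <- c(rep(v[1], hw), v, rep(v[length(v)], hw))
  out <- stats::filter(vp, k, sides = 2)
  as.numeric(out[(hw + 1):(hw + length(v))])
}

#' Integro-differential operator response profile
#'
#' For one candidate center, the absolute Gaussian-blurred radial derivative of
#' the circular mean intensity, evaluated at each radius: |G_sigma * d/dr m(r)|.
#' The derivative uses central differences (one-sided at the ends), so the
#' response is invariant to adding a constant to the image.
#'
#' @param image grayscale matrix.
#' @param x0,y0 candidate center.
#' @param radii ascending radius vector (>= 3 values).
#' @param sigma Gaussian std in radius steps.
#' @param n_angular_samples,arc_mask see [search_config()].
#' @return Numeric vector of responses, one per radius (`NA` where the circle
#'   exits the image).
#' @export
ido_response <- function(image, x0, y0, radii, sigma = 1,
                         n_angular_samples = 128L, arc_mask = NULL) {
  if (length(radii) < 3) {
    iristex_error("need at least 3 radii", "iristex_value_error")
  }
  th <- contour_angles(n_angular_samples, arc_mask)
  m <- circular_means_multi(as_gray_matrix(image), x0, y0, radii, th)
  n <- length(radii)
  dm <- rep(NA_real_, n)
  ok <- !is.na(m)
  if (sum(ok) >= 3) {
    mi <- m; mi[!ok] <- 0
    # central differences on the valid prefix (radii ascending; circles exit
    # the image only beyond some radius, so valid entries form a prefix)
    last <- max(which(ok))
    idx <- which(ok)[1]:last
    v <- m[idx]; r <- radii[idx]
    dv <- numeric(length(v))
    if (length(v) >= 2) {
      dv[1] <- (v[2] - v[1]) / (r[2] - r[1])
      dv[length(v)] <- (v[length(v)] - v[length(v) - 1]) /
        (r[length(v)] - r[length(v) - 1])
    }
    if (length(v) >= 3) {
      k <- 2:(length(v) - 1)
      dv[k] <- (v[k + 1] - v[k - 1]) / (r[k + 1] - r[k - 1])
    }
    dm[idx] <- conv_replicate(dv, gauss_kernel(sigma))
  }
  abs(dm)
}

# Best (center, radius) over explicit center/radius grids. Ties: higher
# response wins; then smaller radius; then row-major center order (the grids
# are iterated in that order and comparison is strict).
ido_search <- function(image, centers_x, centers_y, radii, sigma,
                       n_angular_samples, arc_mask) {
  th <- contour_angles(n_angular_samples, arc_mask)
  best <- list(resp = -Inf, x = NA, y = NA, r = NA)
  for (ci in seq_along(centers_x)) {
    m <- circular_means_multi(image, centers_x[ci], centers_y[ci], radii, th)
    ok <- !is.na(m)
    if (sum(ok) < 3) next
    resp <- ido_response_from_means(m, radii, sigma)
    for (ri in which(!is.na(resp))) {
      if (resp[ri] > best$resp + 1e-12 ||
          (abs(resp[ri] - best$resp) <= 1e-12 && !is.na(best$r) && radii[ri] < best$r)) {
        best <- list(resp = resp[ri], x = centers_x[ci], y = centers_y[ci],
                     r = radii[ri])
      }
    }
  }
  best
}

# Response profile from precomputed means (shared by ido_search; keeps the
# exported ido_response() as the single formula definition).
ido_response_from_means <- function(m, radii, sigma) {
  n <- length(radii)
  dm <- rep(NA_real_, n)
  ok <- !is.na(m)
  if (sum(ok) < 3) return(dm)
  last <- max(which(ok))
  idx <- which(ok)[1]:last
  v <- m[idx]; r <- radii[idx]
  dv <- numeric(length(v))
  dv[1] <- (v[2] - v[1]) / (r[2] - r[1])
  dv[length(v)] <- (v[length(v)] - v[length(v) - 1]) / (r[length(v)] - r[length(v) - 1])
  if (length(v) >= 3) {
    k <- 2:(length(v) - 1)
    dv[k] <- (v[k + 1] - v[k - 1]) / (r[k + 1] - r[k - 1])
  }
  dm[idx] <- abs(conv_replicate(dv, gauss_kernel(sigma)))
  dm
}

# Block-mean downscale by integer factor (trailing remainder rows/cols dropped).
downscale_mean <- function(img, f) {
  nr <- (nrow(img) %/% f) * f; nc <- (ncol(img) %/% f) * f
  img <- img[seq_len(nr), seq_len(nc), drop = FALSE]
  m <- matrix(0, nr %/% f, nc %/% f)
  for (i in seq_len(f)) for (j in seq_len(f)) {
    m <- m + img[seq(i, nr, by = f), seq(j, nc, by = f)]
  }
  m / f^2
}

# Full-resolution center grid within a margin, given stride.
center_grid <- function(nr, nc, margin, stride) {
  lo <- ceiling(1 + margin); hix <- floor(nc - margin); hiy <- floor(nr - margin)
  if (lo > hix || lo > hiy) {
    iristex_error("radius range too large for image", "iristex_config_error")
  }
  gx <- seq(lo, hix, by = stride); gy <- seq(lo, hiy, by = stride)
  # row-major order: y outer, x inner
  list(x = rep(gx, times = length(gy)), y = rep(gy, each = length(gx)))
}

#' Locate the pupil boundary circle
#'
#' Maximizes the integro-differential operator over center and radius. The
#' default `"coarse_to_fine"` method first scans a downscaled image (factor
#' `config$coarse_factor`), then refines the best candidates at full
#' resolution; `"exhaustive"` scans the full-resolution grid directly.
#'
#' @param image grayscale matrix.
#' @param config a [search_config()]; by default radii span
#'   \[min(dim)/40, min(dim)/8\] (anatomical pupil prior).
#' @param method `"coarse_to_fine"` or `"exhaustive"`.
#' @return A [circle()].
#' @export
locate_pupil <- function(image, config = NULL, method = "coarse_to_fine") {
  image <- as_gray_matrix(image)
  if (nrow(image) < 64 || ncol(image) < 64) {
    iristex_error("image must be at least 64x64", "iristex_value_error")
  }
  if (is.null(config)) {
    md <- min(dim(image))
    config <- search_config(radius_min = md / 40, radius_max = md / 8)
  }
  res <- ido_locate(image, config, method, centers = NULL)
  if (res$resp < config$response_floor) {
    iristex_error("no circular boundary found (response below floor)",
                  "iristex_no_circle_error")
  }
  circle(res$x, res$y, res$r)
}

#' Locate the iris (limbus) boundary circle
#'
#' Same objective as [locate_pupil()], with the center constrained near the
#' pupil center and (optionally) eyelid arcs excluded from the contour
#' integral via `config$arc_mask`.
#'
#' @param image grayscale matrix.
#' @param pupil the previously found pupil [circle()].
#' @param config a [search_config()] with `radius_min > pupil$r`; defaults to
#'   radii in \[1.5, 5\] x pupil radius.
#' @param center_slack maximum center offset from the pupil center, pixels.
#' @param method `"coarse_to_fine"` or `"exhaustive"`.
#' @return A [circle()].
#' @export
locate_iris <- function(image, pupil, config = NULL, center_slack = 15,
                        method = "coarse_to_fine") {
  image <- as_gray_matrix(image)
  if (is.null(config)) {
    config <- search_config(radius_min = 1.5 * pupil$r,
                            radius_max = min(5 * pupil$r, min(dim(image)) / 2 - 2))
  }
  if (config$radius_min <= pupil$r) {
    iristex_error("iris radius_min must exceed the pupil radius",
                  "iristex_value_error")
  }
  res <- ido_locate(image, config, method,
                    centers = list(x0 = pupil$x0, y0 = pupil$y0,
                                   slack = center_slack))
  if (res$resp < config$response_floor) {
    iristex_error("no circular boundary found (response below floor)",
                  "iristex_no_circle_error")
  }
  circle(res$x, res$y, res$r)
}

# Shared search driver. centers = NULL -> whole image grid; else a box of
# half-width `slack` around (x0, y0).
ido_locate <- function(image, config, method, centers) {
  nr <- nrow(image); nc <- ncol(image)
  radii_full <- seq(config$radius_min, config$radius_max,
                    by = config$radius_stride)
  grid_full <- function() {
    if (is.null(centers)) {
      center_grid(nr, nc, config$radius_min, config$center_stride)
    } else {
      gx <- seq(max(2, round(centers$x0 - centers$slack)),
                min(nc - 1, round(centers$x0 + centers$slack)),
                by = config$center_stride)
      gy <- seq(max(2, round(centers$y0 - centers$slack)),
                min(nr - 1, round(centers$y0 + centers$slack)),
                by = config$center_stride)
      list(x = rep(gx, times = length(gy)), y = rep(gy, each = length(gx)))
    }
  }

  if (method == "exhaustive") {
    g <- grid_full()
    return(ido_search(image, g$x, g$y, radii_full, config$sigma,
                      config$n_angular_samples, config$arc_mask))
  }

  # keep the coarse image at >= 64 px on its short side: tiny coarse images
  # localize candidates too poorly for the refinement windows
  f <- max(1L, min(config$coarse_factor, min(nr, nc) %/% 64L))
  small <- downscale_mean(image, f)
  r_lo <- max(1.5, config$radius_min / f)
  r_hi <- max(r_lo + 2, config$radius_max / f)
  radii_c <- seq(r_lo, r_hi, by = max(1, config$radius_stride / f))
  if (is.null(centers)) {
    g <- center_grid(nrow(small), ncol(small), r_lo,
                     max(1L, config$center_stride))
    dq <- config$dark_quantile
    if (is.null(dq)) dq <- 0.08
    if (dq < 1) {
      dark <- small[cbind(g$y, g$x)] <= stats::quantile(small, dq)
      if (any(dark)) { g$x <- g$x[dark]; g$y <- g$y[dark] }
    }
  } else {
    gx <- seq(max(2, round((centers$x0 - centers$slack) / f)),
              min(ncol(small) - 1, round((centers$x0 + centers$slack) / f)), by = 1)
    gy <- seq(max(2, round((centers$y0 - centers$slack) / f)),
              min(nrow(small) - 1, round((centers$y0 + centers$slack) / f)), by = 1)
    g <- list(x = rep(gx, times = length(gy)), y = rep(gy, each = length(gx)))
  }
  th_c <- contour_angles(max(64L, config$n_angular_samples %/% 2L),
                         config$arc_mask)
  # coarse pass, vectorized over all centers at once: the circular-mean matrix
  # M (centers x radii) is accumulated one (radius, angle) translation at a
  # time, then differentiated and blurred along the radius axis with a band
  # matrix equivalent to the per-profile Gaussian convolution
  M <- matrix(0, length(g$x), length(radii_c))
  d <- clock_dir(th_c)
  for (ri in seq_along(radii_c)) {
    acc <- numeric(length(g$x))
    for (tk in seq_along(th_c)) {
      acc <- acc + bilinear_interp(small, g$x + radii_c[ri] * d$dx[tk],
                                   g$y + radii_c[ri] * d$dy[tk])
    }
    M[, ri] <- acc / length(th_c)
  }
  valid <- outer(g$x, radii_c, function(x, r) x - r >= 1) &
    outer(g$x, radii_c, function(x, r) x + r <= ncol(small)) &
    outer(g$y, radii_c, function(y, r) y - r >= 1) &
    outer(g$y, radii_c, function(y, r) y + r <= nrow(small))
  nr_c <- length(radii_c)
  Dm <- matrix(0, length(g$x), nr_c)
  Dm[, 1] <- (M[, 2] - M[, 1]) / (radii_c[2] - radii_c[1])
  Dm[, nr_c] <- (M[, nr_c] - M[, nr_c - 1]) / (radii_c[nr_c] - radii_c[nr_c - 1])
  if (nr_c >= 3) {
    k <- 2:(nr_c - 1)
    Dm[, k] <- (M[, k + 1, drop = FALSE] - M[, k - 1, drop = FALSE]) /
      matrix(radii_c[k + 1] - radii_c[k - 1], nrow(Dm), length(k), byrow = TRUE)
  }
  kern <- gauss_kernel(config$sigma)
  hw <- (length(kern) - 1L) %/% 2L
  K <- matrix(0, nr_c, nr_c)
  for (jj in seq_len(nr_c)) {
    src <- pmin(pmax(jj + (-hw):hw, 1L), nr_c) # edge replication
    for (m_i in seq_along(src)) K[src[m_i], jj] <- K[src[m_i], jj] + kern[m_i]
  }
  resp <- abs(Dm %*% K)
  resp[!valid] <- -Inf
  best_r <- max.col(resp, ties.method = "first")
  best_v <- resp[cbind(seq_len(nrow(resp)), best_r)]
  keep <- is.finite(best_v)
  if (!any(keep)) return(list(resp = -Inf, x = NA, y = NA, r = NA))
  cand <- cbind(best_v, g$x, g$y, radii_c[best_r])[keep, , drop = FALSE]
  cand <- cand[order(-cand[, 1]), , drop = FALSE]
  # non-max suppression: keep spatially distinct candidates so one strong
  # spurious edge (or a field of texture pits) cannot crowd out the true
  # boundary before full-resolution re-scoring
  sep <- max(3, 2 * r_lo)
  picked <- matrix(numeric(0), 0, 4)
  for (ci in seq_len(nrow(cand))) {
    if (nrow(picked) == 0 ||
        all((cand[ci, 2] - picked[, 2])^2 + (cand[ci, 3] - picked[, 3])^2 >= sep^2)) {
      picked <- rbind(picked, cand[ci, ])
      if (nrow(picked) >= 48) break
    }
  }
  # safety net: also carry the best candidate whose centre lies in the deepest
  # 2% of intensities (the pupil interior of any eye image), in case texture
  # pits fill the list
  deep_idx <- which(keep & small[cbind(g$y, g$x)] <= stats::quantile(small, 0.02))
  if (length(deep_idx) > 0) {
    di <- deep_idx[which.max(best_v[deep_idx])]
    picked <- rbind(picked, c(best_v[di], g$x[di], g$y[di], radii_c[best_r[di]]))
  }

  # refinement grids snap to the same lattice the exhaustive search scans, so
  # coarse-to-fine and exhaustive agree exactly when center_stride > 1
  lo_phase <- ceiling(1 + config$radius_min)
  snap <- function(v) {
    lo_phase + ceiling((v - lo_phase) / config$center_stride) * config$center_stride
  }
  seq_safe <- function(from, to, by) if (from > to) from else seq(from, to, by = by)
  refine_one <- function(cx, cy, cr, w, n_ang = config$n_angular_samples) {
    gx <- seq_safe(snap(max(2, round(cx) - w)), min(nc - 1, round(cx) + w),
                   config$center_stride)
    gy <- seq_safe(snap(max(2, round(cy) - w)), min(nr - 1, round(cy) + w),
                   config$center_stride)
    rr <- radii_full[radii_full >= cr - 2 * f & radii_full <= cr + 2 * f]
    if (length(rr) < 3) {
      rr <- sort(radii_full[order(abs(radii_full - cr))][seq_len(min(5, length(radii_full)))])
    }
    ido_search(image, rep(gx, times = length(gy)), rep(gy, each = length(gx)),
               rr, config$sigma, n_ang, config$arc_mask)
  }

  # first pass: small full-resolution window around every candidate, at halved
  # angular sampling (the coarse objective over-rewards minimum-radius texture
  # pits, so the ranking must happen at full resolution); second pass: wide
  # window, full sampling, around the three leaders
  mini <- lapply(seq_len(nrow(picked)), function(k) {
    refine_one(picked[k, 2] * f - f / 2, picked[k, 3] * f - f / 2,
               picked[k, 4] * f, w = 3,
               n_ang = max(64L, config$n_angular_samples %/% 2L))
  })
  ord <- order(-vapply(mini, function(m) m$resp, 0))
  best <- list(resp = -Inf, x = NA, y = NA, r = NA)
  for (k in ord[seq_len(min(3, length(ord)))]) {
    res <- refine_one(mini[[k]]$x, mini[[k]]$y, mini[[k]]$r, w = f + 1)
    if (res$resp > best$resp) best <- res
  }
  best
}

#' Segment an eye image into pupil and iris circles
#'
#' Convenience wrapper: locates the pupil, then the iris constrained around it.
#'
#' @param image grayscale matrix.
#' @param pupil_config,iris_config optional [search_config()]s.
#' @return An object of class `"iris_geometry"`: list with `pupil` and `iris`
#'   [circle()]s.
#' @export
segment_eye <- function(image, pupil_config = NULL, iris_config = NULL) {
  pupil <- locate_pupil(image, pupil_config)
  iris <- locate_iris(image, pupil, iris_config)
  structure(list(pupil = pupil, iris = iris), class = "iris_geometry")
}

#' @export
print.iris_geometry <- function(x, ...) {
  cat("iris geometry:\n  pupil: "); print(x$pupil)
  cat("  iris:  "); print(x$iris)
  invisible(x)
}
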