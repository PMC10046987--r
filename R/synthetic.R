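#' Specification of a synthetic eye image
#'
#' Describes the geometry, intensities and class-dependent texture of a
#' generated eye phantom: a bright sclera background, a textured iris annulus
#' and a dark pupil disc. When `label = 1` ("CAD-like"), `lesion_count` dark
#' elliptical spots of contrast `lesion_contrast` are placed inside the angular
#' sector that maps to the heart region of a left iris (2-4 o'clock), so the
#' two classes differ only in the texture statistics of that sector.
#'
#' @param image_height,image_width image size in pixels.
#' @param pupil,iris [circle()] objects; the pupil must lie strictly inside the
#'   iris and the iris strictly inside the image.
#' @param pupil_intensity,iris_base_intensity,sclera_intensity gray-levels in
#'   \[0, 255\]; must be ordered dark pupil < iris < bright sclera.
#' @param fiber_amplitude amplitude (gray-levels) of the sinusoidal radial-fiber
#'   modulation of the iris annulus.
#' @param fiber_frequency fiber count, cycles per revolution.
#' @param lesion_count number of lesions rendered when `label = 1`.
#' @param lesion_contrast gray-level drop at a lesion center.
#' @param label class label: 0 = healthy, 1 = CAD-like.
#' @param seed integer seed controlling all randomness of the rendering.
#' @return An object of class `"eye_spec"`.
#' @export
eye_spec <- function(image_height = 360, image_width = 360,
                     pupil = circle(180, 180, 38),
                     iris = circle(180, 180, 112),
                     pupil_intensity = 30, iris_base_intensity = 110,
                     sclera_intensity = 220,
                     fiber_amplitude = 18, fiber_frequency = 24,
                     lesion_count = 10, lesion_contrast = 60,
                     label = 0L, seed = 1L) {
  spec <- structure(list(
    image_height = as.integer(image_height), image_width = as.integer(image_width),
    pupil = pupil, iris = iris,
    pupil_intensity = pupil_intensity, iris_base_intensity = iris_base_intensity,
    sclera_intensity = sclera_intensity,
    fiber_amplitude = fiber_amplitude, fiber_frequency = fiber_frequency,
    lesion_count = as.integer(lesion_count), lesion_contrast = lesion_contrast,
    label = as.integer(label), seed = as.integer(seed)
  ), class = "eye_spec")
  validate_eye_spec(spec)
  spec
}

validate_eye_spec <- function(spec) {
  p <- spec$pupil; i <- spec$iris
  off <- sqrt((p$x0 - i$x0)^2 + (p$y0 - i$y0)^2)
  if (off + p$r >= i$r) {
    iristex_error("pupil circle must lie strictly inside the iris circle",
                  "iristex_geometry_error")
  }
  if (!circle_in_image(i, spec$image_height, spec$image_width)) {
    iristex_error("iris circle must lie strictly inside the image bounds",
                  "iristex_geometry_error")
  }
  if (!(spec$pupil_intensity < spec$iris_base_intensity &&
        spec$iris_base_intensity < spec$sclera_intensity)) {
    iristex_error("intensities must satisfy pupil < iris < sclera",
                  "iristex_geometry_error")
  }
  if (spec$lesion_count < 0) {
    iristex_error("lesion_count must be >= 0", "iristex_geometry_error")
  }
  invisible(spec)
}

# Angular sector (radians, clock convention) of the heart region of a left
# iris: 2 to 4 o'clock. Lesions are kept on an inner margin of the sector and
# of the default ROI radial window so they land inside the cropped ROI.
heart_sector <- function() c(2, 4) * pi / 6

#' Render a synthetic eye image
#'
#' Deterministic given `spec$seed`: two calls with the same spec return
#' bit-identical images. The iris annulus carries a sinusoidal angular fiber
#' texture plus low-amplitude smoothed noise; lesions (if any) are placed in
#' polar coordinates inside the heart sector and rendered into Cartesian space.
#'
#' @param spec an [eye_spec()].
#' @return A list with `image` (numeric matrix, gray-levels 0-255) and
#'   `spec` (the ground truth used).
#' @export
generate_eye <- function(spec) {
  validate_eye_spec(spec)
  with_seed(spec$seed, {
    nr <- spec$image_height; nc <- spec$image_width
    xs <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    ys <- matrix(seq_len(nr), nr, nc)
    ic <- spec$iris; pc <- spec$pupil
    d_iris <- sqrt((xs - ic$x0)^2 + (ys - ic$y0)^2)
    d_pupil <- sqrt((xs - pc$x0)^2 + (ys - pc$y0)^2)
    # clock angle of each pixel about the iris center
    theta <- atan2(xs - ic$x0, -(ys - ic$y0)) %% (2 * pi)

    img <- matrix(spec$sclera_intensity, nr, nc)
    in_iris <- d_iris <= ic$r
    fibers <- spec$fiber_amplitude *
      sin(spec$fiber_frequency * theta + 2 * pi * stats::runif(1))
    noise <- matrix(stats::rnorm(nr * nc), nr, nc)
    noise <- smooth_separable(noise, 2) * (spec$fiber_amplitude / 3)
    iris_tex <- spec$iris_base_intensity + fibers + noise
    img[in_iris] <- iris_tex[in_iris]

    if (spec$label == 1L && spec$lesion_count > 0L && spec$lesion_contrast != 0) {
      sect <- heart_sector()
      marg <- 0.1 * (sect[2] - sect[1])
      th_c <- stats::runif(spec$lesion_count, sect[1] + marg, sect[2] - marg)
      # radial fraction within the default ROI radial window (rows 60-249 of
      # 360), with margin for lesion extent
      fr_c <- stats::runif(spec$lesion_count, 0.22, 0.62)
      ax_a <- stats::runif(spec$lesion_count, 3, 6)
      ax_b <- stats::runif(spec$lesion_count, 2, 4.5)
      rot <- stats::runif(spec$lesion_count, 0, pi)
      for (l in seq_len(spec$lesion_count)) {
        dirs <- clock_dir(th_c[l])
        rad <- pc$r + fr_c[l] * (ic$r - pc$r) # concentric approximation
        # exact rubber-sheet inverse: interpolate between boundary points
        xp <- pc$x0 + pc$r * sin(th_c[l]); yp <- pc$y0 - pc$r * cos(th_c[l])
        xl <- ic$x0 + ic$r * sin(th_c[l]); yl <- ic$y0 - ic$r * cos(th_c[l])
        cx <- (1 - fr_c[l]) * xp + fr_c[l] * xl
        cy <- (1 - fr_c[l]) * yp + fr_c[l] * yl
        u <- (xs - cx) * cos(rot[l]) + (ys - cy) * sin(rot[l])
        v <- -(xs - cx) * sin(rot[l]) + (ys - cy) * cos(rot[l])
        bump <- exp(-0.5 * ((u / ax_a[l])^2 + (v / ax_b[l])^2))
        bump[bump < exp(-4.5)] <- 0 # truncate at 3 sigma: no long tails
        img <- img - spec$lesion_contrast * bump * in_iris
      }
    }

    img[d_pupil <= pc$r] <- spec$pupil_intensity
    img <- round(pmin(pmax(img, 0), 255))
    list(image = img, spec = spec)
  })
}

# Separable box smoothing (radius w), edges padded by replication.
smooth_separable <- function(m, w) {
  k <- rep(1, 2 * w + 1) / (2 * w + 1)
  pad <- function(v) c(rep(v[1], w), v, rep(v[length(v)], w))
  m <- apply(m, 2, function(v) stats::filter(pad(v), k)[(w + 1):(w + length(v))])
  m <- t(apply(m, 1, function(v) stats::filter(pad(v), k)[(w + 1):(w + length(v))]))
  m
}

#' Generate a two-class synthetic cohort
#'
#' Produces `2 * n_per_class` eye images with randomized geometry and
#' intensities drawn within fixed ranges. The two classes differ only by the
#' lesion texture perturbation of magnitude `effect` (gray-levels) confined to
#' the heart-ROI sector; `effect = 0` makes the classes statistically
#' indistinguishable.
#'
#' @param n_per_class images per class (>= 1).
#' @param effect lesion contrast (gray-level delta) of the CAD-like class.
#' @param seed integer seed.
#' @return An object of class `"synthetic_cohort"`: list with `images`
#'   (list of matrices), `truths` (list of [eye_spec()]), `labels`
#'   (integer vector of 0/1).
#' @export
generate_cohort <- function(n_per_class, effect = 60, seed = 1L) {
  if (n_per_class < 1) {
    iristex_error("n_per_class must be >= 1", "iristex_value_error")
  }
  n <- 2L * as.integer(n_per_class)
  labels <- rep(c(0L, 1L), each = n_per_class)
  specs <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      cx <- stats::runif(1, 170, 190); cy <- stats::runif(1, 170, 190)
      pr <- stats::runif(1, 32, 44)
      ir <- stats::runif(1, 100, 124)
      # small pupil/iris center offset, as in real eyes
      px <- cx + stats::runif(1, -3, 3); py <- cy + stats::runif(1, -3, 3)
      eye_spec(
        image_height = 360, image_width = 360,
        pupil = circle(px, py, pr), iris = circle(cx, cy, ir),
        pupil_intensity = stats::runif(1, 25, 35),
        iris_base_intensity = stats::runif(1, 100, 120),
        sclera_intensity = stats::runif(1, 210, 230),
        fiber_amplitude = 18, fiber_frequency = round(stats::runif(1, 20, 28)),
        lesion_count = 10L, lesion_contrast = effect,
        label = labels[i],
        seed = sample.int(.Machine$integer.max, 1)
      )
    })
  })
  images <- lapply(specs, function(s) generate_eye(s)$image)
  structure(list(images = images, truths = specs, labels = labels),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d images (%d healthy, %d CAD-like), %dx%d px\n",
              length(x$images), sum(x$labels == 0), sum(x$labels == 1),
              nrow(x$images[[1]]), ncol(x$images[[1]])))
  invisible(x)
}

#' Small integer fixture matrices for brute-force texture oracles
#'
#' Named list of tiny integer matrices with hand-checkable co-occurrence and
#' run-length structure: a constant 5x5, a two-level 4x4 checkerboard, the
#' single-row run image (0,0,0,1,1), and a fixed pseudo-random 8x8 with 8 gray
#' levels (hard-coded, identical across calls).
#'
#' @return Named list of integer matrices.
#' @export
toy_matrices <- function() {
  checker <- outer(0:3, 0:3, function(i, j) (i + j) %% 2L)
  rand8 <- matrix(c(
    2L, 6L, 1L, 4L, 0L, 7L, 3L, 5L,
    5L, 0L, 7L, 2L, 6L, 1L, 4L, 3L,
    1L, 3L, 4L, 6L, 2L, 5L, 0L, 7L,
    7L, 2L, 0L, 5L, 3L, 4L, 6L, 1L,
    4L, 5L, 6L, 0L, 7L, 2L, 1L, 3L,
    0L, 7L, 3L, 1L, 4L, 6L, 5L, 2L,
    6L, 1L, 5L, 7L, 0L, 3L, 2L, 4L,
    3L, 4L, 2L, 6L, 5L, 0L, 7L, 1L
  ), nrow = 8, byrow = TRUE)
  list(
    constant5 = matrix(3L, 5, 5),
    checker4 = checker,
    run_row = matrix(c(0L, 0L, 0L, 1L, 1L), nrow = 1),
    random8 = rand8
  )
}

#' Write a synthetic cohort to disk
#'
#' Saves each image as an 8-bit grayscale PNG and a CSV manifest with the
#' ground-truth geometry (columns: filename, label, pupil_x, pupil_y, pupil_r,
#' iris_x, iris_y, iris_r, seed).
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest data frame.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- length(cohort$images)
  fn <- sprintf("eye_%03d.png", seq_len(n))
  for (i in seq_len(n)) {
    write_eye_image(cohort$images[[i]], file.path(dir, fn[i]))
  }
  manifest <- data.frame(
    filename = fn,
    label = cohort$labels,
    pupil_x = vapply(cohort$truths, function(s) s$pupil$x0, 0),
    pupil_y = vapply(cohort$truths, function(s) s$pupil$y0, 0),
    pupil_r = vapply(cohort$truths, function(s) s$pupil$r, 0),
    iris_x = vapply(cohort$truths, function(s) s$iris$x0, 0),
    iris_y = vapply(cohort$truths, function(s) s$iris$y0, 0),
    iris_r = vapply(cohort$truths, function(s) s$iris$r, 0),
    seed = vapply(cohort$truths, function(s) s$seed, 0L)
  )
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
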