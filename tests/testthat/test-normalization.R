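geom_concentric <- function() {
  structure(list(pupil = circle(180, 180, 40), iris = circle(180, 180, 120)),
            class = "iris_geometry")
}

test_that("rubber sheet has the fixed output size and correct boundary rows", {
  eye <- generate_eye(eye_spec(seed = 7))
  g <- list(pupil = eye$spec$pupil, iris = eye$spec$iris)
  norm <- rubber_sheet(eye$image, g)
  expect_equal(dim(norm), c(360L, 720L))
  # row 1 = samples on the pupil circle boundary
  th <- 2 * pi * (0:719) / 720
  xp <- g$pupil$x0 + g$pupil$r * sin(th)
  yp <- g$pupil$y0 - g$pupil$r * cos(th)
  bilin <- function(img, x, y) { # independent transcription
    x0 <- floor(x); y0 <- floor(y); fx <- x - x0; fy <- y - y0
    (1 - fy) * ((1 - fx) * img[y0, x0] + fx * img[y0, x0 + 1]) +
      fy * ((1 - fx) * img[y0 + 1, x0] + fx * img[y0 + 1, x0 + 1])
  }
  expected <- vapply(seq_len(720), function(j) bilin(eye$image, xp[j], yp[j]), 0)
  expect_equal(as.vector(unclass(norm)[1, ]), expected, tolerance = 1e-9)
})

test_that("radially constant concentric pattern unwraps to constant columns", {
  xs <- matrix(seq_len(360), 360, 360, byrow = TRUE)
  ys <- matrix(seq_len(360), 360, 360)
  th <- atan2(xs - 180, -(ys - 180)) %% (2 * pi)
  img <- 100 + 50 * sin(6 * th) # constant along each radius
  norm <- rubber_sheet(img, geom_concentric())
  col_spread <- apply(unclass(norm), 2, function(v) diff(range(v)))
  expect_lt(max(col_spread), 2.5) # interpolation error only
})

test_that("unwrapping recovers a known smooth polar pattern within 2 gray RMS", {
  # render an analytic pattern g(radial fraction, angle) into Cartesian space,
  # unwrap it, and compare against g evaluated on the polar grid directly
  g_fun <- function(fr, th) 120 + 40 * sin(4 * th) + 30 * cos(2 * pi * 2 * fr)
  xs <- matrix(seq_len(360), 360, 360, byrow = TRUE)
  ys <- matrix(seq_len(360), 360, 360)
  d <- sqrt((xs - 180)^2 + (ys - 180)^2)
  th <- atan2(xs - 180, -(ys - 180)) %% (2 * pi)
  fr <- pmin(pmax((d - 40) / (120 - 40), 0), 1)
  img <- g_fun(fr, th)
  norm <- rubber_sheet(img, geom_concentric())
  expected <- outer((0:359) / 359, 2 * pi * (0:719) / 720, g_fun)
  rms <- sqrt(mean((unclass(norm) - expected)^2))
  expect_lt(rms, 2)
})

test_that("ROI crop is exact slicing with the 190x120 default window", {
  norm <- rubber_sheet(generate_eye(eye_spec(seed = 2))$image, geom_concentric())
  roi <- crop_heart_roi(norm)
  expect_equal(dim(roi), c(190L, 120L))
  expect_identical(roi[1, 1], unclass(norm)[61, 121]) # rows 60-249, cols 120-239 (0-based)
  expect_identical(roi, unclass(norm)[61:250, 121:240])
})

test_that("marker painted at 3 o'clock mid-radius lands inside the ROI", {
  spec <- eye_spec(seed = 8)
  eye <- generate_eye(spec)$image
  # forward-map (theta = 90 deg, radial fraction 0.5) through the boundary
  # interpolation used by the rubber sheet
  th <- pi / 2
  xp <- spec$pupil$x0 + spec$pupil$r * sin(th); yp <- spec$pupil$y0 - spec$pupil$r * cos(th)
  xl <- spec$iris$x0 + spec$iris$r * sin(th); yl <- spec$iris$y0 - spec$iris$r * cos(th)
  mx <- round(0.5 * xp + 0.5 * xl); my <- round(0.5 * yp + 0.5 * yl)
  eye[my + (-1:1), mx + (-1:1)] <- 255
  g <- list(pupil = spec$pupil, iris = spec$iris)
  roi <- crop_heart_roi(rubber_sheet(eye, g))
  expect_gt(max(roi), 250)

  # the same marker at 8 o'clock must NOT appear in the heart ROI
  eye2 <- generate_eye(spec)$image
  th <- 8 * pi / 6
  xp <- spec$pupil$x0 + spec$pupil$r * sin(th); yp <- spec$pupil$y0 - spec$pupil$r * cos(th)
  xl <- spec$iris$x0 + spec$iris$r * sin(th); yl <- spec$iris$y0 - spec$iris$r * cos(th)
  mx <- round(0.5 * xp + 0.5 * xl); my <- round(0.5 * yp + 0.5 * yl)
  eye2[my + (-1:1), mx + (-1:1)] <- 255
  roi2 <- crop_heart_roi(rubber_sheet(eye2, g))
  expect_lt(max(roi2), 250)
})

test_that("ROI windows wrap around 12 o'clock and reject out-of-bounds specs", {
  norm <- rubber_sheet(generate_eye(eye_spec(seed = 1))$image, geom_concentric())
  wrap <- crop_heart_roi(norm, roi_spec(clock_start = 11, clock_end = 13))
  expect_equal(dim(wrap), c(190L, 120L))
  expect_identical(wrap[, 1:60], unclass(norm)[61:250, 661:720])
  expect_identical(wrap[, 61:120], unclass(norm)[61:250, 1:60])
  expect_error(crop_heart_roi(norm, roi_spec(radial_row_start = 300)),
               class = "iristex_value_error")
})

test_that("CLAHE keeps shape and range, leaves constants alone, spreads ramps", {
  roi <- matrix(120, 190, 120)
  expect_identical(enhance_clahe(roi), roi)
  ramp <- matrix(rep(seq(100, 120, length.out = 120), each = 190), 190, 120)
  out <- enhance_clahe(ramp)
  expect_equal(dim(out), dim(ramp))
  expect_true(all(out >= 0 & out <= 255))
  expect_gt(stats::sd(out), stats::sd(ramp)) # contrast expanded
  expect_error(clahe_params(clip_limit = 0), class = "iristex_config_error")
})
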