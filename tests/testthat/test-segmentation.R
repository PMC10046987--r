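test_that("circular mean matches constants, nested discs and a quadrature oracle", {
  img <- matrix(100, 128, 128)
  expect_equal(circular_mean_intensity(img, circle(64, 64, 30)), 100)

  disc <- phantom_eye(pupil = circle(64, 64, 50), iris = circle(64, 64, 55),
                      levels = c(30, 30, 200)) # dark disc r=50 on bright bg
  expect_equal(circular_mean_intensity(disc, circle(64, 64, 25)), 30)

  # off-center circle straddling the disc edge: between the two levels, and
  # matching dense numerical quadrature
  circ <- circle(95, 64, 25)
  v <- circular_mean_intensity(disc, circ, n_angular_samples = 4096)
  expect_gt(v, 30); expect_lt(v, 200)
  expect_equal(v, circular_mean_oracle(disc, 95, 64, 25), tolerance = 1e-3)

  expect_error(circular_mean_intensity(img, circle(5, 64, 30)),
               class = "iristex_out_of_bounds_error")
})

test_that("ido_response is zero on constants, peaks at step edges, ignores offsets", {
  img <- matrix(77, 128, 128)
  r <- ido_response(img, 64, 64, 10:40)
  expect_true(all(abs(r) < 1e-9))

  disc <- phantom_eye(pupil = circle(64, 64, 30), iris = circle(64, 64, 35),
                      levels = c(40, 40, 200))
  radii <- 20:45
  resp <- ido_response(disc, 64, 64, radii)
  expect_equal(radii[which.max(resp)], 30, tolerance = 1) # within one stride

  resp_shift <- ido_response(disc + 30, 64, 64, radii)
  expect_equal(resp, resp_shift, tolerance = 1e-9)

  expect_error(ido_response(img, 64, 64, c(10, 11)), class = "iristex_value_error")
})

test_that("pupil and iris are recovered on a synthetic eye within 2 px", {
  eye <- generate_eye(eye_spec(image_height = 400, image_width = 420,
                               pupil = circle(200, 220, 40),
                               iris = circle(200, 220, 120), seed = 3))
  g <- segment_eye(eye$image)
  expect_lt(max(abs(c(g$pupil$x0 - 200, g$pupil$y0 - 220, g$pupil$r - 40))), 2)
  expect_lt(max(abs(c(g$iris$x0 - 200, g$iris$y0 - 220, g$iris$r - 120))), 2)
})

test_that("uniform image yields no circle; preconditions are enforced", {
  img <- matrix(128, 128, 128)
  expect_error(locate_pupil(img), class = "iristex_no_circle_error")
  expect_error(locate_iris(img, circle(64, 64, 30),
                           search_config(radius_min = 20, radius_max = 60)),
               class = "iristex_value_error") # radius_min <= pupil r
  expect_error(locate_pupil(matrix(0, 32, 32)), class = "iristex_value_error")
})

test_that("two nested edges: pupil search returns the inner one", {
  img <- phantom_eye() # pupil r=18 at (64,66), iris r=48 at (64,64)
  cfg <- search_config(radius_min = 8, radius_max = 30) # pupil-scale range
  p <- locate_pupil(img, cfg)
  expect_lt(max(abs(c(p$x0 - 64, p$y0 - 66, p$r - 18))), 2)
  i <- locate_iris(img, p)
  expect_lt(max(abs(c(i$x0 - 64, i$y0 - 64, i$r - 48))), 2)
})

test_that("iris is found from unmasked arcs when the top quarter is painted over", {
  img <- phantom_eye()
  img[1:40, ] <- 230 # occlude the upper arcs (eyelid-like)
  p <- locate_pupil(img, search_config(radius_min = 8, radius_max = 30))
  cfg <- search_config(radius_min = 1.6 * p$r, radius_max = 60,
                       arc_mask = list(c(315, 45), c(135, 225)))
  i <- locate_iris(img, p, cfg)
  expect_lt(max(abs(c(i$x0 - 64, i$y0 - 64, i$r - 48))), 2)
})

test_that("coarse-to-fine equals exhaustive search on a 128x128 phantom", {
  img <- phantom_eye()
  cfg <- search_config(radius_min = 8, radius_max = 30, center_stride = 2)
  a <- locate_pupil(img, cfg, method = "coarse_to_fine")
  b <- locate_pupil(img, cfg, method = "exhaustive")
  expect_equal(c(a$x0, a$y0, a$r), c(b$x0, b$y0, b$r))
})

test_that("found centers are translation-equivariant", {
  base <- phantom_eye(nr = 150, nc = 150, pupil = circle(70, 70, 18),
                      iris = circle(70, 70, 48))
  shifted <- phantom_eye(nr = 150, nc = 150, pupil = circle(76, 74, 18),
                         iris = circle(76, 74, 48))
  cfg <- search_config(radius_min = 8, radius_max = 30)
  p1 <- locate_pupil(base, cfg); p2 <- locate_pupil(shifted, cfg)
  expect_equal(p2$x0 - p1$x0, 6, tolerance = 1)
  expect_equal(p2$y0 - p1$y0, 4, tolerance = 1)
  expect_equal(p2$r, p1$r, tolerance = 1)
})
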