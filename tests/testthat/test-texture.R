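test_that("quantization bins by min-max, clamps to range and handles constants", {
  band <- matrix(c(0, 64, 128, 255), 2, 2)
  q <- quantize(band, 8)
  # level = floor(value * 8 / 256) for the 0..255 span (max clamped to 7)
  expect_equal(as.vector(q), c(0L, 2L, 4L, 7L))
  expect_true(all(quantize(matrix(5, 3, 3), 8) == 0L))
  neg <- matrix(c(-3, -1, 0, 6), 2, 2)
  qn <- quantize(neg, 4)
  expect_true(all(qn >= 0 & qn <= 3))
  expect_equal(qn[1, 1], 0L); expect_equal(qn[2, 2], 3L)
  expect_error(quantize(band, 1), class = "iristex_value_error")
})

test_that("co-occurrence probabilities match hand enumeration and normalize", {
  q <- matrix(c(0L, 0L, 1L, 1L), 2, 2, byrow = TRUE)
  attr(q, "L") <- 2L
  P <- glcm(q, 0) # two horizontal pairs: (0,0) and (1,1)
  expect_equal(P[1, 1], 0.5); expect_equal(P[2, 2], 0.5)
  expect_equal(P[1, 2] + P[2, 1], 0)
  expect_equal(sum(P), 1)
  # constant image: single entry 1
  qc <- quantize(matrix(9, 4, 4), 8)
  Pc <- glcm(qc, 90)
  expect_equal(Pc[1, 1], 1)
  expect_error(glcm(quantize(matrix(1:2, 1), 2), 90),
               class = "iristex_empty_glcm_error")
})

test_that("co-occurrence matrix and features match the brute-force oracle on all fixtures", {
  for (nm in names(toy_matrices())) {
    m <- toy_matrices()[[nm]]
    L <- max(max(m) + 1L, 2L)
    q <- m; attr(q, "L") <- L
    for (th in c(0, 45, 90, 135)) {
      if (nm == "run_row" && th != 0) next # single row: only horizontal pairs
      P <- glcm(q, th)
      expect_equal(unclass(P), glcm_oracle(m, L, th), tolerance = 1e-15,
                   ignore_attr = TRUE)
      expect_equal(as.numeric(glcm_features(P)), glcm_features_oracle(unclass(P)),
                   tolerance = 1e-12)
    }
  }
})

test_that("checkerboard and single-entry matrices give the classic feature values", {
  q <- toy_matrices()$checker4; attr(q, "L") <- 2L
  f <- glcm_features(glcm(q, 0))
  expect_equal(unname(f["contrast"]), 1)
  expect_equal(unname(f["dissimilarity"]), 1)
  expect_equal(unname(f["energy"]), 0.5)
  P1 <- structure(matrix(c(1, 0, 0, 0), 2, 2), class = c("glc_matrix", "matrix"))
  f1 <- glcm_features(P1)
  expect_equal(unname(f1[c("energy", "entropy", "contrast", "homogeneity",
                           "maximum_probability")]), c(1, 0, 0, 1, 1))
  expect_true(attr(f1, "degenerate"))
  expect_length(f, 22)
  expect_identical(names(f), glcm_feature_names())
})

test_that("rotating the image by 90 degrees swaps the 0- and 90-degree features", {
  m <- toy_matrices()$random8
  q <- m; attr(q, "L") <- 8L
  rot <- t(m[nrow(m):1, ]) # 90-degree rotation
  qr <- rot; attr(qr, "L") <- 8L
  f0 <- glcm_features(glcm(q, 0))
  f90r <- glcm_features(glcm(qr, 90))
  expect_equal(f0, f90r, tolerance = 1e-12)
})

test_that("run-length matrices match hand counts and the pixel-partition identity", {
  q <- toy_matrices()$run_row; attr(q, "L") <- 2L
  R <- glrlm(q, 0)
  expect_equal(R[1, 3], 1L); expect_equal(R[2, 2], 1L)
  expect_equal(sum(unclass(R)), 2L)

  for (nm in names(toy_matrices())) {
    m <- toy_matrices()[[nm]]
    L <- max(max(m) + 1L, 2L)
    q <- m; attr(q, "L") <- L
    for (th in c(0, 45, 90, 135)) {
      R <- glrlm(q, th)
      expect_equal(unclass(R), glrlm_oracle(m, L, th), ignore_attr = TRUE)
      # runs tile every pixel exactly once
      expect_equal(sum(t(t(unclass(R)) * seq_len(ncol(R)))), length(m))
    }
  }
})

test_that("run-length features match hand evaluation and the oracle", {
  q <- toy_matrices()$run_row; attr(q, "L") <- 2L
  f <- glrlm_features(glrlm(q, 0))
  expect_equal(unname(f["sre"]), (1 / 9 + 1 / 4) / 2)
  expect_equal(unname(f["lre"]), 6.5)
  expect_equal(unname(f["rp"]), 2 / 5)

  qc <- matrix(0L, 5, 5); attr(qc, "L") <- 2L
  fc <- glrlm_features(glrlm(qc, 0)) # 5 runs of length 5
  expect_equal(unname(fc["lre"]), 25)
  expect_equal(unname(fc["rp"]), 5 / 25)

  ck <- toy_matrices()$checker4; attr(ck, "L") <- 2L
  fk <- glrlm_features(glrlm(ck, 0)) # all runs length 1
  expect_equal(unname(fk[c("sre", "lre", "rp")]), c(1, 1, 1))

  for (nm in names(toy_matrices())) {
    m <- toy_matrices()[[nm]]
    L <- max(max(m) + 1L, 2L)
    q <- m; attr(q, "L") <- L
    R <- glrlm(q, 45)
    expect_equal(unname(glrlm_features(R)),
                 glrlm_features_oracle(unclass(R), length(m)), tolerance = 1e-12)
  }
})

test_that("first-order statistics match direct evaluation and conventions", {
  expect_equal(unname(first_order_stats(matrix(5, 3, 3))), c(5, 0, 0, 0, 0))
  f <- first_order_stats(c(1, 2, 3, 4))
  expect_equal(unname(f["mean"]), 2.5)
  expect_equal(unname(f["std"]), sqrt(5 / 3), tolerance = 1e-9) # 1.29099
  m2 <- mean((1:4 - 2.5)^2); m4 <- mean((1:4 - 2.5)^4)
  expect_equal(unname(f["skewness"]), 0)
  expect_equal(unname(f["kurtosis"]), m4 / m2^2)
  # balanced two-valued data: 1 bit of histogram entropy
  expect_equal(unname(first_order_stats(rep(c(0, 1), 8))["entropy"]), 1)
})

test_that("directional averaging is the arithmetic mean and validates input", {
  v <- c(a = 1, b = 2)
  expect_equal(directional_average(list(v, v, v, v)), v)
  expect_equal(unname(directional_average(list(1, 2, 3, 6))), 3)
  expect_error(directional_average(list(1, 2, 3)), class = "iristex_value_error")
})

test_that("the feature vector has 136 stable named values, 34 per band", {
  roi <- matrix(generate_eye(eye_spec(seed = 3))$image[100:180, 100:160], 81, 61)
  fv <- extract_feature_vector(roi)
  expect_length(fv, 136)
  expect_identical(names(fv), feature_names())
  expect_equal(sum(startsWith(names(fv), "cA_")), 34)
  expect_identical(fv, extract_feature_vector(roi)) # deterministic
  expect_false(anyNA(fv))
})

test_that("near-isotropic noise gives similar contrast in all four directions", {
  set.seed(1)
  band <- matrix(rnorm(120 * 120), 120, 120)
  q <- quantize(band, 8)
  contrasts <- vapply(c(0, 45, 90, 135),
                      function(th) glcm_features(glcm(q, th))[["contrast"]], 0)
  expect_lt(diff(range(contrasts)) / mean(contrasts), 0.1)
})
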