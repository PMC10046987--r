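#' Unwrap the iris annulus to polar coordinates (rubber-sheet model)
#'
#' Maps the annulus between the pupil and iris circles to a fixed-size
#' rectangle. Output row `i` corresponds to the radial fraction
#' `r = (i-1)/(out_rows-1)` (row 1 = pupil boundary, last row = iris boundary);
#' output column `j` to the clock angle `theta = (j-1) * 2*pi/out_cols`
#' (column 1 = 12 o'clock, increasing clockwise as displayed). Each output
#' pixel is the bilinear sample of the source image at the point linearly
#' interpolated between the pupil- and iris-circle boundary points along
#' `theta`; this accommodates non-concentric pupil/iris circles.
#'
#' @param image grayscale matrix.
#' @param geometry an `"iris_geometry"` (list with `pupil`, `iris` circles).
#' @param out_rows,out_cols output size (default 360 x 720).
#' @return An object of class `"normalized_iris"`: an `out_rows x out_cols`
#'   matrix with attribute `valid` (logical matrix, `FALSE` where the sample
#'   point fell outside the image and was filled by the nearest edge value).
#' @export
rubber_sheet <- function(image, geometry, out_rows = 360L, out_cols = 720L) {
  image <- as_gray_matrix(image)
  p <- geometry$pupil; l <- geometry$iris
  th <- 2 * pi * (seq_len(out_cols) - 1) / out_cols
  d <- clock_dir(th)
  xp <- p$x0 + p$r * d$dx; yp <- p$y0 + p$r * d$dy
  xl <- l$x0 + l$r * d$dx; yl <- l$y0 + l$r * d$dy
  r <- (seq_len(out_rows) - 1) / (out_rows - 1)
  X <- outer(1 - r, xp) + outer(r, xl)
  Y <- outer(1 - r, yp) + outer(r, yl)
  valid <- X >= 1 & X <= ncol(image) & Y >= 1 & Y <= nrow(image)
  vals <- bilinear_interp(image, as.vector(X), as.vector(Y))
  out <- matrix(vals, out_rows, out_cols)
  attr(out, "valid") <- matrix(valid, out_rows, out_cols)
  class(out) <- c("normalized_iris", class(out))
  out
}

#' Region-of-interest window on the normalized iris
#'
#' The heart region of the left-iris map lies between the 2 and 4 o'clock
#' positions. With 720 angular columns (0.5 degrees per column) that 60-degree
#' sector is exactly 120 columns; the default radial window of 190 rows starts
#' at row index 60 (0-based), skipping the pupil-border ring and the limbus.
#'
#' @param clock_start,clock_end sector bounds in clock hours.
#' @param radial_row_start first radial row of the window (0-based).
#' @param n_radial_rows,n_angular_cols window size (default 190 x 120).
#' @return An object of class `"roi_spec"`.
#' @export
roi_spec <- function(clock_start = 2, clock_end = 4, radial_row_start = 60L,
                     n_radial_rows = 190L, n_angular_cols = 120L) {
  structure(list(clock_start = clock_start, clock_end = clock_end,
                 radial_row_start = as.integer(radial_row_start),
                 n_radial_rows = as.integer(n_radial_rows),
                 n_angular_cols = as.integer(n_angular_cols)),
            class = "roi_spec")
}

#' Crop the heart-sector ROI from a normalized iris
#'
#' Pure sub-matrix extraction (no resampling): angular columns are taken from
#' `clock_start * 60` (0-based, 2 columns per degree) with wrap-around modular
#' arithmetic, radial rows from `radial_row_start`.
#'
#' @param norm a [rubber_sheet()] output (or any matrix of the same layout).
#' @param spec a [roi_spec()].
#' @return `n_radial_rows x n_angular_cols` matrix (default 190 x 120).
#' @export
crop_heart_roi <- function(norm, spec = roi_spec()) {
  nr <- nrow(norm); nc <- ncol(norm)
  cols_per_hour <- nc / 12
  col0 <- round(spec$clock_start * cols_per_hour) # 0-based
  rows <- spec$radial_row_start + seq_len(spec$n_radial_rows) # 1-based
  if (rows[length(rows)] > nr || spec$radial_row_start < 0) {
    iristex_error("ROI radial window out of bounds", "iristex_value_error")
  }
  if (spec$n_angular_cols > nc) {
    iristex_error("ROI angular window wider than the normalized iris",
                  "iristex_value_error")
  }
  cols <- ((col0 + seq_len(spec$n_angular_cols) - 1) %% nc) + 1
  out <- unclass(norm)[rows, cols, drop = FALSE]
  attributes(out) <- list(dim = dim(out))
  out
}

#' CLAHE parameters
#'
#' @param tile_rows,tile_cols tile grid (>= 1).
#' @param clip_limit contrast-limiting clip factor (> 0).
#' @return An object of class `"clahe_params"`.
#' @export
clahe_params <- function(tile_rows = 8L, tile_cols = 8L, clip_limit = 2) {
  if (tile_rows < 1 || tile_cols < 1 || clip_limit <= 0) {
    iristex_error("invalid CLAHE parameters", "iristex_config_error")
  }
  structure(list(tile_rows = as.integer(tile_rows),
                 tile_cols = as.integer(tile_cols), clip_limit = clip_limit),
            class = "clahe_params")
}

#' Contrast-limited adaptive histogram equalization of a ROI
#'
#' Per-tile histogram equalization with a clip limit and bilinear inter-tile
#' blending (delegated to EBImage). Input and output are gray-level matrices in
#' \[0, 255\]; constant inputs stay constant.
#'
#' @param roi gray-level matrix.
#' @param params a [clahe_params()].
#' @return Matrix of the same shape, gray-levels in \[0, 255\].
#' @export
enhance_clahe <- function(roi, params = clahe_params()) {
  roi <- as_gray_matrix(roi)
  if (max(roi) == min(roi)) return(roi) # no contrast to redistribute
  # pad by edge replication to a multiple of the tile grid (required by the
  # tiled equalization), crop back afterwards
  nr <- nrow(roi); nc <- ncol(roi)
  pr <- (params$tile_rows - nr %% params$tile_rows) %% params$tile_rows
  pc <- (params$tile_cols - nc %% params$tile_cols) %% params$tile_cols
  padded <- roi[c(seq_len(nr), rep(nr, pr)), c(seq_len(nc), rep(nc, pc)),
                drop = FALSE]
  # EBImage images are indexed [x, y]: transpose in and out
  img <- EBImage::Image(t(padded) / 255, colormode = "Grayscale")
  out <- EBImage::clahe(img, nx = params$tile_cols, ny = params$tile_rows,
                        bins = 256, limit = params$clip_limit)
  out <- t(EBImage::imageData(out))[seq_len(nr), seq_len(nc)] * 255
  pmin(pmax(out, 0), 255)
}
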