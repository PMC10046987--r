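#' @keywords internal
"_PACKAGE"

# Error constructors used across modules. Conditions carry a subclass so tests
# and callers can distinguish failure causes without matching message text.
iristex_error <- function(msg, class) {
  stop(structure(
    class = c(class, "iristex_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so package functions are deterministic without clobbering the
#' user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Bilinear interpolation into a grayscale image matrix
#'
#' Image convention throughout the package: a numeric matrix with rows = image
#' rows (y, downwards) and columns = image columns (x, rightwards), gray-levels
#' in \[0, 255\]. Coordinates are 1-based; points outside the image are clamped
#' to the nearest edge pixel.
#'
#' @param img numeric matrix.
#' @param x,y numeric vectors of equal length (column and row coordinates).
#' @return numeric vector of interpolated intensities.
#' @keywords internal
bilinear_interp <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x <- pmin(pmax(x, 1), nc)
  y <- pmin(pmax(y, 1), nr)
  x0 <- pmin(floor(x), nc - 1L); x1 <- x0 + 1
  y0 <- pmin(floor(y), nr - 1L); y1 <- y0 + 1
  fx <- x - x0; fy <- y - y0
  i00 <- img[cbind(y0, x0)]; i01 <- img[cbind(y0, x1)]
  i10 <- img[cbind(y1, x0)]; i11 <- img[cbind(y1, x1)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

# Unit direction for a clock angle theta (radians): 0 at 12 o'clock, increasing
# clockwise as displayed. In matrix/image coordinates (y grows downward) this is
# dx = sin(theta), dy = -cos(theta).
clock_dir <- function(theta) list(dx = sin(theta), dy = -cos(theta))

#' Circle in image pixel coordinates
#'
#' @param x0,y0 center (column, row), pixels.
#' @param r radius, pixels (> 0).
#' @return An object of class `"iris_circle"`.
#' @export
circle <- function(x0, y0, r) {
  if (!is.finite(r) || r <= 0) {
    iristex_error("circle radius must be positive", "iristex_geometry_error")
  }
  structure(list(x0 = as.numeric(x0), y0 = as.numeric(y0), r = as.numeric(r)),
            class = "iris_circle")
}

#' @export
print.iris_circle <- function(x, ...) {
  cat(sprintf("circle: center (%.2f, %.2f), r = %.2f px\n", x$x0, x$y0, x$r))
  invisible(x)
}

circle_in_image <- function(circ, nr, nc, margin = 0) {
  circ$x0 - circ$r >= 1 + margin && circ$x0 + circ$r <= nc - margin &&
    circ$y0 - circ$r >= 1 + margin && circ$y0 + circ$r <= nr - margin
}

as_gray_matrix <- function(img) {
  if (is.matrix(img)) return(img)
  iristex_error("expected a 2-D grayscale matrix", "iristex_io_error")
}
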