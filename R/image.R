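#' Single-channel grayscale image
#'
#' The universal currency of the package: a 2-D matrix of integer gray
#' levels in `[0, 2^depth - 1]`, stored row = image row. Values outside the
#' range are clipped and non-integers rounded at ingestion, so every
#' downstream histogram sees valid intensities.
#'
#' @param pixels Numeric matrix of intensities.
#' @param depth Bits per pixel; gray levels run from 0 to `2^depth - 1`.
#'   Default 8.
#' @return An object of class `gray_image`: the integer pixel matrix with a
#'   `depth` attribute.
#' @examples
#' img <- gray_image(matrix(0:255, 16, 16))
#' dim(img)
#' @export
gray_image <- function(pixels, depth = 8L) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("pixels must be a numeric matrix")
  }
  if (length(pixels) == 0L) stop("empty input")
  depth <- as.integer(depth)
  if (depth < 1L) stop("depth must be a positive integer")
  maxv <- 2^depth - 1
  px <- round(pixels)
  px[px < 0] <- 0
  px[px > maxv] <- maxv
  structure(px, depth = depth, class = c("gray_image", "matrix", "array"))
}

#' Coerce to a grayscale image
#'
#' Accepts a `gray_image`, a plain numeric matrix (interpreted on the
#' `[0, 2^depth - 1]` scale), a matrix of unit-interval values as returned
#' by PNG/TIFF readers (detected and rescaled), or a 3-D RGB array, which is
#' converted to luminance with ITU-R BT.601 weights (0.299, 0.587, 0.114).
#' Matrices with values beyond an 8-bit range are linearly rescaled to
#' `[0, 255]` so that all computation shares one code path.
#'
#' @param x Object to coerce.
#' @param depth Target bit depth (default 8).
#' @return A [gray_image()].
#' @export
as_gray_image <- function(x, depth = 8L) {
  if (inherits(x, "gray_image")) {
    if (attr(x, "depth") == depth) return(x)
    sc <- (2^depth - 1) / (2^attr(x, "depth") - 1)
    return(gray_image(unclass(x) * sc, depth = depth))
  }
  if (is.array(x) && length(dim(x)) == 3L) {
    w <- c(0.299, 0.587, 0.114)
    nch <- dim(x)[3]
    if (nch >= 3L) {
      x <- w[1] * x[, , 1] + w[2] * x[, , 2] + w[3] * x[, , 3]
    } else {
      x <- x[, , 1]
    }
  }
  if (!is.matrix(x) || !is.numeric(x)) stop("cannot coerce to gray_image")
  maxv <- 2^depth - 1
  mx <- max(x)
  mn <- min(x)
  if (mx <= 1 && mn >= 0 && mx > 0) {
    # unit-interval raster from an image reader
    x <- x * maxv
  } else if (mx > maxv || mn < 0) {
    # deeper or signed data: rescale linearly onto the working range
    if (mx > mn) x <- (x - mn) / (mx - mn) * maxv else x <- x * 0
  }
  gray_image(x, depth = depth)
}

# strip class/attributes for arithmetic
pixel_matrix <- function(img) {
  if (inherits(img, "gray_image")) {
    m <- unclass(img)
    attr(m, "depth") <- NULL
    return(m)
  }
  if (is.matrix(img) && is.numeric(img)) return(img)
  stop("expected a gray_image or numeric matrix")
}

image_depth <- function(img) {
  d <- attr(img, "depth")
  if (is.null(d)) 8L else as.integer(d)
}

check_same_dim <- function(...) {
  dims <- lapply(list(...), dim)
  ref <- dims[[1]]
  for (d in dims[-1]) {
    if (!identical(as.integer(d), as.integer(ref))) stop("shape mismatch")
  }
  invisible(ref)
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, %d-bit, range [%d, %d]>\n",
              nrow(x), ncol(x), image_depth(x), min(x), max(x)))
  invisible(x)
}
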