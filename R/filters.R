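# Low-level spatial filtering on plain matrices. Borders use symmetric
# (whole-sample, edge-repeating) reflection throughout, applied by index
# folding so kernels wider than the image remain valid.

fold_index <- function(i, n) {
  repeat {
    below <- i < 1L
    above <- i > n
    if (!any(below) && !any(above)) return(i)
    i[below] <- 1L - i[below]
    i[above] <- 2L * n + 1L - i[above]
  }
}

# 1-D correlation along rows (margin = 1) or columns (margin = 2)
conv_axis <- function(m, k, margin) {
  len <- length(k)
  if (len == 1L) return(m * k)
  r <- (len - 1L) %/% 2L
  n <- if (margin == 1L) nrow(m) else ncol(m)
  idx <- fold_index(seq.int(1L - r, n + (len - 1L) - r), n)
  mp <- if (margin == 1L) m[idx, , drop = FALSE] else m[, idx, drop = FALSE]
  out <- matrix(0, nrow(m), ncol(m))
  for (t in seq_len(len)) {
    out <- out + k[t] * (if (margin == 1L) {
      mp[t:(t + nrow(m) - 1L), , drop = FALSE]
    } else {
      mp[, t:(t + ncol(m) - 1L), drop = FALSE]
    })
  }
  out
}

conv_sep <- function(m, k) conv_axis(conv_axis(m, k, 1L), k, 2L)

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

gaussian_blur_matrix <- function(m, sigma) {
  if (sigma <= 0) return(m)
  conv_sep(m, gaussian_kernel(sigma))
}

#' Gaussian blur of a grayscale image
#'
#' Separable Gaussian filter with symmetric border reflection; the kernel
#' radius is `ceiling(3 * sigma)` pixels.
#'
#' @param img A [gray_image()] or numeric matrix.
#' @param sigma Standard deviation in pixels; `sigma <= 0` returns the input
#'   unchanged.
#' @return A [gray_image()] with the depth of the input.
#' @export
gaussian_blur <- function(img, sigma) {
  img <- as_gray_image(img)
  if (sigma <= 0) return(img)
  gray_image(gaussian_blur_matrix(pixel_matrix(img), sigma),
             depth = image_depth(img))
}

box_mean <- function(m, radius) {
  k <- rep(1, 2L * radius + 1L) / (2L * radius + 1L)
  conv_sep(m, k)
}

# 3x3 Laplacian response (4-neighbour stencil)
laplacian_response <- function(m) {
  up    <- conv_axis(m, c(1, 0, 0), 1L)
  down  <- conv_axis(m, c(0, 0, 1), 1L)
  left  <- conv_axis(m, c(1, 0, 0), 2L)
  right <- conv_axis(m, c(0, 0, 1), 2L)
  up + down + left + right - 4 * m
}

#' Mean absolute Laplacian sharpness
#'
#' A simple focus measure: the mean absolute response of the 4-neighbour
#' Laplacian stencil, optionally over a logical region mask.
#'
#' @param img A [gray_image()] or numeric matrix.
#' @param mask Optional logical matrix selecting the region to average over.
#' @return Mean absolute Laplacian (gray levels).
#' @export
sharpness <- function(img, mask = NULL) {
  m <- pixel_matrix(as_gray_image(img))
  l <- abs(laplacian_response(m))
  if (is.null(mask)) mean(l) else mean(l[mask])
}

# Sobel gradient: list(gx, gy, mag, ang) with ang in (-pi/2, pi/2]
sobel_gradient <- function(m) {
  smooth <- c(1, 2, 1)
  diff   <- c(-1, 0, 1)
  gx <- conv_axis(conv_axis(m, smooth, 1L), diff, 2L)
  gy <- conv_axis(conv_axis(m, smooth, 2L), diff, 1L)
  mag <- sqrt(gx^2 + gy^2)
  ang <- matrix(0, nrow(m), ncol(m))
  nzx <- gx != 0
  ang[nzx] <- atan(gy[nzx] / gx[nzx])
  zx <- !nzx & gy != 0
  ang[zx] <- sign(gy[zx]) * pi / 2
  list(gx = gx, gy = gy, mag = mag, ang = ang)
}
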