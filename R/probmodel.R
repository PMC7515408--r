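#' Discrete probability distribution
#'
#' A normalized gray-level histogram: nonnegative masses summing to one
#' (checked to 1e-12 after an exact renormalization of counting drift).
#'
#' @param p Numeric vector of probabilities (or unnormalized nonnegative
#'   weights whose sum is within 1e-8 of one).
#' @return Object of class `prob_dist`: numeric vector with attribute
#'   `n_bins`.
#' @export
prob_dist <- function(p) {
  p <- as.numeric(p)
  if (length(p) < 1L) stop("empty distribution")
  if (any(p < 0)) stop("negative probability")
  s <- sum(p)
  if (abs(s - 1) > 1e-8) stop("probabilities must sum to 1")
  structure(p / s, n_bins = length(p), class = "prob_dist")
}

#' Joint probability distribution over two gray-level axes
#'
#' @param pj Nonnegative `N x N` matrix summing to one (within 1e-8 before
#'   exact renormalization).
#' @return Object of class `joint_dist` with attribute `n_bins`.
#' @export
joint_dist <- function(pj) {
  if (!is.matrix(pj) || nrow(pj) != ncol(pj)) {
    stop("joint distribution must be a square matrix")
  }
  if (any(pj < 0)) stop("negative probability")
  s <- sum(pj)
  if (abs(s - 1) > 1e-8) stop("probabilities must sum to 1")
  structure(pj / s, n_bins = nrow(pj), class = c("joint_dist", "matrix", "array"))
}

bin_indices <- function(img, bins) {
  img <- as_gray_image(img)
  levels <- 2^image_depth(img)
  ix <- floor(pixel_matrix(img) * (bins / levels))
  ix[ix > bins - 1] <- bins - 1
  as.integer(ix) + 1L
}

#' Marginal gray-level histogram
#'
#' Counts pixels into `bins` equal-width intensity bins covering the full
#' `[0, 2^depth - 1]` range and normalizes by the pixel count — plain
#' counting, no smoothing or interpolation.
#'
#' @param img A [gray_image()] or numeric matrix.
#' @param bins Number of bins (default 256, the full 8-bit range).
#' @return A [prob_dist()] of length `bins`.
#' @examples
#' marginal_hist(gray_image(matrix(c(0, 0, 255, 255), 2)))[c(1, 256)]
#' @export
marginal_hist <- function(img, bins = 256L) {
  if (length(img) == 0L) stop("empty input")
  bins <- as.integer(bins)
  if (is.na(bins) || bins < 2L) stop("invalid bins")
  idx <- bin_indices(img, bins)
  counts <- tabulate(idx, nbins = bins)
  prob_dist(counts / sum(counts))
}

#' Joint gray-level histogram of two co-registered images
#'
#' Cell `(i, j)` holds the fraction of pixel positions whose intensities in
#' `img1` and `img2` fall into bins `i` and `j` respectively. Row sums
#' reproduce `marginal_hist(img1)` and column sums `marginal_hist(img2)`
#' exactly, because both are built from the same integer counts.
#'
#' @param img1,img2 Images of identical dimensions.
#' @param bins Bins per axis (default 256).
#' @return A [joint_dist()] of dimension `bins x bins`.
#' @export
joint_hist <- function(img1, img2, bins = 256L) {
  if (length(img1) == 0L || length(img2) == 0L) stop("empty input")
  bins <- as.integer(bins)
  if (is.na(bins) || bins < 2L) stop("invalid bins")
  img1 <- as_gray_image(img1)
  img2 <- as_gray_image(img2)
  check_same_dim(img1, img2)
  i1 <- bin_indices(img1, bins)
  i2 <- bin_indices(img2, bins)
  lin <- i1 + (i2 - 1L) * bins
  counts <- tabulate(lin, nbins = bins * bins)
  joint_dist(matrix(counts / sum(counts), nrow = bins, ncol = bins))
}
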