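# Six classical fusion algorithms used as stimuli for the quality metrics:
# pixel averaging, PCA weighting, Laplacian and contrast pyramids,
# block-DCT selection, and guided-filter two-scale fusion. These exist to
# exercise the metrics, not to reproduce any particular third-party
# implementation.

#' A pair of source images plus labeled fusion candidates
#'
#' @param a,b Co-registered source images of equal dimensions.
#' @param fused Named list of fused images (unique labels, same
#'   dimensions as the sources).
#' @return Object of class `fusion_set`.
#' @export
fusion_set <- function(a, b, fused = list()) {
  a <- as_gray_image(a); b <- as_gray_image(b)
  check_same_dim(a, b)
  if (length(fused)) {
    if (is.null(names(fused)) || any(names(fused) == "") ||
        anyDuplicated(names(fused))) {
      stop("fused images must carry unique labels")
    }
    fused <- lapply(fused, as_gray_image)
    for (f in fused) check_same_dim(a, f)
  }
  structure(list(a = a, b = b, fused = fused), class = "fusion_set")
}

fused_list <- function(fused) {
  if (inherits(fused, "fusion_set")) return(fused$fused)
  if (inherits(fused, "gray_image")) return(list(fused = fused))
  if (is.list(fused)) {
    if (is.null(names(fused)) || any(names(fused) == "") ||
        anyDuplicated(names(fused))) {
      stop("fused images must carry unique labels")
    }
    return(lapply(fused, as_gray_image))
  }
  stop("expected a fusion_set or a named list of images")
}

fusion_pair <- function(a, b) {
  a <- as_gray_image(a); b <- as_gray_image(b)
  check_same_dim(a, b)
  list(a = pixel_matrix(a), b = pixel_matrix(b), depth = image_depth(a))
}

clip_depth <- function(m, depth) gray_image(m, depth = depth)

#' Pixel-average fusion
#'
#' The simplest rule: each output pixel is the mean of the two inputs.
#'
#' @param a,b Source images of equal dimensions.
#' @return Fused [gray_image()].
#' @export
fuse_average <- function(a, b) {
  p <- fusion_pair(a, b)
  clip_depth((p$a + p$b) / 2, p$depth)
}

#' PCA-weighted fusion
#'
#' Computes the 2x2 covariance of the flattened images and weights them by
#' the components of its principal eigenvector, normalized to sum to one.
#' If the eigenvector has mixed signs the weights fall back to being
#' proportional to the image variances.
#'
#' @param a,b Source images; at least one must be non-constant.
#' @return Fused [gray_image()].
#' @export
fuse_pca <- function(a, b) {
  p <- fusion_pair(a, b)
  cv <- stats::cov(cbind(as.vector(p$a), as.vector(p$b)))
  if (all(abs(cv) < .Machine$double.eps)) stop("degenerate covariance")
  v <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  if (all(v >= 0) || all(v <= 0)) {
    w <- abs(v) / sum(abs(v))
  } else {
    vars <- diag(cv)
    w <- vars / sum(vars)
  }
  clip_depth(w[1] * p$a + w[2] * p$b, p$depth)
}

# --- pyramids -------------------------------------------------------------

# 5-tap binomial kernel
pyr_kernel <- c(1, 4, 6, 4, 1) / 16

pyr_reduce <- function(m) {
  sm <- conv_sep(m, pyr_kernel)
  sm[seq(1L, nrow(m), 2L), seq(1L, ncol(m), 2L), drop = FALSE]
}

pyr_expand <- function(m, target_dim) {
  z <- matrix(0, target_dim[1], target_dim[2])
  z[seq(1L, target_dim[1], 2L), seq(1L, target_dim[2], 2L)] <- m
  conv_axis(conv_axis(z, 2 * pyr_kernel, 1L), 2 * pyr_kernel, 2L)
}

gaussian_pyramid <- function(m, levels) {
  g <- vector("list", levels + 1L)
  g[[1L]] <- m
  for (l in seq_len(levels)) g[[l + 1L]] <- pyr_reduce(g[[l]])
  g
}

check_pyramid_size <- function(dims, levels) {
  if (levels < 1L) stop("levels must be at least 1")
  if (min(ceiling(dims / 2^levels)) < 2L) stop("image too small for levels")
}

#' Laplacian-pyramid fusion
#'
#' Both images are decomposed into a Laplacian pyramid (5-tap binomial
#' kernel, reflective borders). Detail coefficients are fused by
#' maximum-absolute-value selection, the coarsest base level is averaged,
#' and the fused pyramid is collapsed back to an image.
#'
#' @param a,b Source images of equal dimensions.
#' @param levels Number of detail levels (default 4).
#' @return Fused [gray_image()].
#' @export
fuse_laplacian_pyramid <- function(a, b, levels = 4L) {
  p <- fusion_pair(a, b)
  check_pyramid_size(dim(p$a), levels)
  ga <- gaussian_pyramid(p$a, levels)
  gb <- gaussian_pyramid(p$b, levels)
  fused <- vector("list", levels + 1L)
  for (l in seq_len(levels)) {
    ea <- pyr_expand(ga[[l + 1L]], dim(ga[[l]]))
    eb <- pyr_expand(gb[[l + 1L]], dim(gb[[l]]))
    la <- ga[[l]] - ea
    lb <- gb[[l]] - eb
    pick_a <- abs(la) >= abs(lb)
    fused[[l]] <- ifelse(pick_a, la, lb)
  }
  fused[[levels + 1L]] <- (ga[[levels + 1L]] + gb[[levels + 1L]]) / 2
  out <- fused[[levels + 1L]]
  for (l in rev(seq_len(levels))) {
    out <- fused[[l]] + pyr_expand(out, dim(fused[[l]]))
  }
  clip_depth(out, p$depth)
}

#' Contrast-pyramid fusion
#'
#' Ratio-of-lowpass pyramid: at each level the contrast image
#' `C = G_l / expand(G_{l+1})` is formed (an offset of one gray level keeps
#' the ratios finite), the coefficient with the larger deviation `|C - 1|`
#' is selected, the coarsest base is averaged, and the image is rebuilt
#' multiplicatively.
#'
#' @inheritParams fuse_laplacian_pyramid
#' @return Fused [gray_image()].
#' @export
fuse_contrast_pyramid <- function(a, b, levels = 4L) {
  p <- fusion_pair(a, b)
  check_pyramid_size(dim(p$a), levels)
  ga <- gaussian_pyramid(p$a + 1, levels)  # offset keeps every lowpass > 0
  gb <- gaussian_pyramid(p$b + 1, levels)
  fused <- vector("list", levels + 1L)
  for (l in seq_len(levels)) {
    ea <- pyr_expand(ga[[l + 1L]], dim(ga[[l]]))
    eb <- pyr_expand(gb[[l + 1L]], dim(gb[[l]]))
    ca <- ga[[l]] / ea
    cb <- gb[[l]] / eb
    pick_a <- abs(ca - 1) >= abs(cb - 1)
    fused[[l]] <- ifelse(pick_a, ca, cb)
  }
  fused[[levels + 1L]] <- (ga[[levels + 1L]] + gb[[levels + 1L]]) / 2
  out <- fused[[levels + 1L]]
  for (l in rev(seq_len(levels))) {
    out <- fused[[l]] * pyr_expand(out, dim(fused[[l]]))
  }
  clip_depth(out - 1, p$depth)
}

# --- block DCT ------------------------------------------------------------

dct_matrix <- function(n) {
  C <- matrix(0, n, n)
  for (u in 0:(n - 1)) {
    cu <- if (u == 0) sqrt(1 / n) else sqrt(2 / n)
    C[u + 1, ] <- cu * cos((2 * (0:(n - 1)) + 1) * u * pi / (2 * n))
  }
  C
}

pad_replicate <- function(m, block) {
  h <- nrow(m); w <- ncol(m)
  H <- ceiling(h / block) * block
  W <- ceiling(w / block) * block
  m[c(seq_len(h), rep(h, H - h)), c(seq_len(w), rep(w, W - w)), drop = FALSE]
}

#' Block-DCT fusion
#'
#' Decomposes both images into `block x block` tiles (default 8, edges
#' padded by replication), takes the 2-D DCT of each tile, and per tile
#' keeps the coefficient set of the image with the larger AC energy — the
#' sharper, higher-variance block — while averaging the DC coefficients.
#' The fused tiles are inverse-transformed and cropped back.
#'
#' @param a,b Source images of equal dimensions, at least `block` pixels
#'   on each side.
#' @param block Tile size (default 8).
#' @return Fused [gray_image()].
#' @export
fuse_dct <- function(a, b, block = 8L) {
  p <- fusion_pair(a, b)
  if (min(dim(p$a)) < block) stop("image smaller than DCT block")
  pa <- pad_replicate(p$a, block)
  pb <- pad_replicate(p$b, block)
  C <- dct_matrix(block)
  Ct <- t(C)
  out <- matrix(0, nrow(pa), ncol(pa))
  for (i in seq(1L, nrow(pa), block)) {
    for (j in seq(1L, ncol(pa), block)) {
      ri <- i:(i + block - 1L); cj <- j:(j + block - 1L)
      da <- C %*% pa[ri, cj] %*% Ct
      db <- C %*% pb[ri, cj] %*% Ct
      dc <- (da[1, 1] + db[1, 1]) / 2
      ea <- sum(da^2) - da[1, 1]^2
      eb <- sum(db^2) - db[1, 1]^2
      d <- if (ea >= eb) da else db
      d[1, 1] <- dc
      out[ri, cj] <- Ct %*% d %*% C
    }
  }
  clip_depth(out[seq_len(nrow(p$a)), seq_len(ncol(p$a)), drop = FALSE],
             p$depth)
}

# --- guided-filter two-scale fusion ---------------------------------------

# Guided filter via box means; I is the guide, p the input,
# both on whatever scale the caller uses (eps must match I's scale^2).
guided_filter <- function(I, p, radius, eps) {
  mI <- box_mean(I, radius)
  mp <- box_mean(p, radius)
  cII <- box_mean(I * I, radius)
  cIp <- box_mean(I * p, radius)
  varI <- cII - mI^2
  covIp <- cIp - mI * mp
  A <- covIp / (varI + eps)
  B <- mp - A * mI
  box_mean(A, radius) * I + box_mean(B, radius)
}

#' Guided-filter two-scale fusion
#'
#' Each image is split into a base layer (box mean) and a detail residual.
#' Per-pixel saliency is the Gaussian-smoothed absolute Laplacian; the
#' binary saliency-argmax weight maps are refined by guided filtering with
#' the source image as guide — a large radius / large `eps` pair for the
#' base layer and a small pair for the detail layer — then normalized to
#' sum to one and used to blend the layers.
#'
#' @param a,b Source images of equal dimensions.
#' @param base_radius,base_eps Guided-filter parameters for the base-layer
#'   weights (`eps` on the unit intensity scale; default 31 and 1e-3).
#' @param detail_radius,detail_eps Parameters for the detail-layer weights
#'   (default 7 and 1e-6).
#' @param mean_radius Radius of the box mean defining the base layer
#'   (default 15).
#' @param saliency_sigma Gaussian smoothing of the absolute-Laplacian
#'   saliency (default 5 pixels).
#' @return Fused [gray_image()].
#' @export
fuse_guided_filter <- function(a, b, base_radius = 31L, base_eps = 1e-3,
                               detail_radius = 7L, detail_eps = 1e-6,
                               mean_radius = 15L, saliency_sigma = 5) {
  p <- fusion_pair(a, b)
  maxv <- 2^p$depth - 1
  ia <- p$a / maxv
  ib <- p$b / maxv
  base_a <- box_mean(ia, mean_radius)
  base_b <- box_mean(ib, mean_radius)
  det_a <- ia - base_a
  det_b <- ib - base_b
  sal_a <- gaussian_blur_matrix(abs(laplacian_response(ia)), saliency_sigma)
  sal_b <- gaussian_blur_matrix(abs(laplacian_response(ib)), saliency_sigma)
  pa <- (sal_a >= sal_b) * 1
  pb <- 1 - pa
  wba <- pmin(pmax(guided_filter(ia, pa, base_radius, base_eps), 0), 1)
  wbb <- pmin(pmax(guided_filter(ib, pb, base_radius, base_eps), 0), 1)
  wda <- pmin(pmax(guided_filter(ia, pa, detail_radius, detail_eps), 0), 1)
  wdb <- pmin(pmax(guided_filter(ib, pb, detail_radius, detail_eps), 0), 1)
  sb <- wba + wbb
  sd <- wda + wdb
  wba <- ifelse(sb > 0, wba / sb, 0.5); wbb <- ifelse(sb > 0, wbb / sb, 0.5)
  wda <- ifelse(sd > 0, wda / sd, 0.5); wdb <- ifelse(sd > 0, wdb / sd, 0.5)
  fused <- (wba * base_a + wbb * base_b) + (wda * det_a + wdb * det_b)
  clip_depth(fused * maxv, p$depth)
}

#' Apply all six classical fusion methods
#'
#' Convenience wrapper producing a [fusion_set()] with candidates labeled
#' `average`, `pca`, `lp`, `cp`, `dct`, `gf`.
#'
#' @param a,b Source images of equal dimensions.
#' @param levels Pyramid levels for LP/CP.
#' @return A [fusion_set()].
#' @export
fuse_all <- function(a, b, levels = 4L) {
  fusion_set(a, b, list(
    average = fuse_average(a, b),
    pca     = fuse_pca(a, b),
    lp      = fuse_laplacian_pyramid(a, b, levels),
    cp      = fuse_contrast_pyramid(a, b, levels),
    dct     = fuse_dct(a, b),
    gf      = fuse_guided_filter(a, b)
  ))
}
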