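# Deterministic, seedable generator of synthetic image pairs with the
# statistical structure the fusion metrics rely on: multi-focus pairs with
# complementary sharp regions around one latent sharp scene, and
# multi-modal pairs that re-render shared latent structure through
# different monotone intensity maps with modality-exclusive content (the
# CT/MR situation). The caller's RNG state is never disturbed.

local_seed <- function(seed, fn) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  fn()
}

#' Specification of a synthetic image pair
#'
#' Holds every knob of the generator; identical specs (including `seed`)
#' produce bit-identical images.
#'
#' @param height,width Image dimensions in pixels (default 256 x 256, the
#'   typical size of the benchmark pairs).
#' @param seed Integer RNG seed.
#' @param scene Latent-scene style: `"mixed"` (smooth field + gratings +
#'   shapes, the default), `"texture"`, or `"shapes"`.
#' @param blur_sigma Gaussian defocus blur in pixels for multi-focus pairs
#'   (default 3; 0 leaves the latent scene untouched).
#' @param split How the defocused region is chosen: `"left-right"`,
#'   `"quadrant"`, or `"mask"` (smooth random mask).
#' @param modality_gamma Gamma of the second modality's intensity remap
#'   (default 2; the first modality uses gamma 1).
#' @param exclusive_fraction Fraction of pixels carrying modality-exclusive
#'   content in multi-modal pairs (default 0.25).
#' @return Object of class `synth_spec`.
#' @export
synth_spec <- function(height = 256L, width = 256L, seed = 0L,
                       scene = c("mixed", "texture", "shapes"),
                       blur_sigma = 3, split = c("left-right", "quadrant",
                                                 "mask"),
                       modality_gamma = 2, exclusive_fraction = 0.25) {
  scene <- match.arg(scene)
  split <- match.arg(split)
  if (blur_sigma < 0) stop("blur_sigma must be nonnegative")
  if (modality_gamma <= 0) stop("modality_gamma must be positive")
  if (exclusive_fraction < 0 || exclusive_fraction > 1) {
    stop("exclusive_fraction must lie in [0, 1]")
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 seed = as.integer(seed), scene = scene,
                 blur_sigma = blur_sigma, split = split,
                 modality_gamma = modality_gamma,
                 exclusive_fraction = exclusive_fraction),
            class = "synth_spec")
}

# components of the latent scene, on an arbitrary continuous scale
scene_field <- function(h, w) {
  sigma <- max(4, min(h, w) / 32)
  f <- gaussian_blur_matrix(matrix(stats::rnorm(h * w), h, w), sigma)
  f / stats::sd(f)
}

scene_gratings <- function(h, w, n = 3L) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  g <- matrix(0, h, w)
  for (i in seq_len(n)) {
    freq <- stats::runif(1, 0.02, 0.12)
    th <- stats::runif(1, 0, pi)
    ph <- stats::runif(1, 0, 2 * pi)
    g <- g + sin(2 * pi * freq * (cos(th) * cols + sin(th) * rows) + ph)
  }
  g / n
}

scene_shapes <- function(h, w, n = 10L) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  s <- matrix(0, h, w)
  for (i in seq_len(n)) {
    cy <- stats::runif(1, 1, h); cx <- stats::runif(1, 1, w)
    ry <- stats::runif(1, h / 16, h / 4); rx <- stats::runif(1, w / 16, w / 4)
    amp <- stats::runif(1, -1.5, 1.5)
    if (stats::runif(1) < 0.5) {
      inside <- ((rows - cy) / ry)^2 + ((cols - cx) / rx)^2 <= 1
    } else {
      inside <- abs(rows - cy) <= ry & abs(cols - cx) <= rx
    }
    s[inside] <- s[inside] + amp
  }
  s
}

#' Generate the latent sharp scene
#'
#' A full-range procedural image with edges at multiple scales: a smooth
#' random field, sinusoidal gratings, and random filled shapes, combined
#' according to `spec$scene` and rescaled to `[0, 255]`.
#'
#' @param spec A [synth_spec()].
#' @return A [gray_image()]; bit-identical for identical specs.
#' @export
make_latent_scene <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  h <- spec$height; w <- spec$width
  if (h < 32L || w < 32L) stop("scene dimensions must be at least 32 pixels")
  local_seed(spec$seed, function() {
    img <- switch(spec$scene,
      mixed   = scene_field(h, w) + 0.7 * scene_gratings(h, w) +
                1.1 * scene_shapes(h, w),
      texture = scene_field(h, w) + scene_gratings(h, w, n = 4L),
      shapes  = 0.3 * scene_field(h, w) + scene_shapes(h, w, n = 14L)
    )
    rng <- range(img)
    gray_image((img - rng[1]) / (rng[2] - rng[1]) * 255)
  })
}

focus_mask <- function(spec) {
  h <- spec$height; w <- spec$width
  switch(spec$split,
    "left-right" = {
      m <- matrix(FALSE, h, w); m[, seq_len(w %/% 2)] <- TRUE; m
    },
    quadrant = {
      rows <- matrix(seq_len(h), h, w)
      cols <- matrix(seq_len(w), h, w, byrow = TRUE)
      (rows <= h / 2) == (cols <= w / 2)
    },
    mask = local_seed(spec$seed + 7L, function() {
      f <- gaussian_blur_matrix(matrix(stats::rnorm(h * w), h, w),
                                min(h, w) / 16)
      f >= stats::median(f)
    })
  )
}

#' Generate a multi-focus pair with ground truth
#'
#' The latent sharp scene is the ground truth; image `a` is defocused
#' (Gaussian blur of `spec$blur_sigma` pixels) inside the focus region and
#' image `b` in its complement, so each source is sharper than the other on
#' complementary regions — the structure of a two-camera multi-focus
#' acquisition.
#'
#' @param spec A [synth_spec()].
#' @return List with elements `a`, `b`, `truth` ([gray_image()]s) and
#'   `mask` (logical matrix of the region blurred in `a`).
#' @export
make_multifocus_pair <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  truth <- make_latent_scene(spec)
  if (spec$blur_sigma == 0) {
    return(list(a = truth, b = truth, truth = truth,
                mask = matrix(FALSE, spec$height, spec$width)))
  }
  tp <- pixel_matrix(truth)
  blurred <- pixel_matrix(gaussian_blur(truth, spec$blur_sigma))
  mask <- focus_mask(spec)
  ap <- tp; ap[mask] <- blurred[mask]
  bp <- tp; bp[!mask] <- blurred[!mask]
  list(a = gray_image(ap), b = gray_image(bp), truth = truth, mask = mask)
}

#' Generate a multi-modal (CT/MR-like) pair
#'
#' Both modalities re-render one latent structure through monotone gamma
#' maps (`gamma = 1` for `a`, `spec$modality_gamma` for `b`), then each
#' receives exclusive content — an independent procedural scene composited
#' over `spec$exclusive_fraction` of its pixels — mimicking tissue visible
#' to only one sensor. The shared structure guarantees joint-histogram
#' dependence between the two outputs.
#'
#' @param spec A [synth_spec()].
#' @return List with images `a` and `b`.
#' @export
make_multimodal_pair <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  latent <- pixel_matrix(make_latent_scene(spec)) / 255
  a <- 255 * latent              # gamma 1
  b <- 255 * latent^spec$modality_gamma
  f <- spec$exclusive_fraction
  if (f > 0) {
    excl_a <- pixel_matrix(make_latent_scene(modify_seed(spec, 1001L)))
    excl_b <- pixel_matrix(make_latent_scene(modify_seed(spec, 2002L)))
    mask_a <- exclusive_mask(spec, 3003L, f)
    mask_b <- exclusive_mask(spec, 4004L, f)
    a[mask_a] <- excl_a[mask_a]
    b[mask_b] <- excl_b[mask_b]
  }
  list(a = gray_image(a), b = gray_image(b))
}

modify_seed <- function(spec, offset) {
  s <- spec
  s$seed <- spec$seed + as.integer(offset)
  s
}

exclusive_mask <- function(spec, offset, fraction) {
  if (fraction >= 1) {
    return(matrix(TRUE, spec$height, spec$width))
  }
  local_seed(spec$seed + offset, function() {
    f <- gaussian_blur_matrix(
      matrix(stats::rnorm(spec$height * spec$width), spec$height, spec$width),
      min(spec$height, spec$width) / 16)
    f >= stats::quantile(f, 1 - fraction)
  })
}

#' Build a blur degradation ladder
#'
#' Progressively Gaussian-blurred copies of a reference image, ordered by
#' blur strength — a quality ladder on which any information-preserving
#' fusion metric should be monotonically decreasing.
#'
#' @param truth Reference image.
#' @param sigmas Strictly increasing blur levels in pixels; the first may
#'   be 0 (the reference itself).
#' @return Named list of [gray_image()]s labeled `sigma_<value>` in ladder
#'   order.
#' @export
make_degradation_ladder <- function(truth, sigmas) {
  if (any(diff(sigmas) <= 0)) stop("sigmas must be strictly increasing")
  if (any(sigmas < 0)) stop("sigmas must be nonnegative")
  truth <- as_gray_image(truth)
  out <- lapply(sigmas, function(s) gaussian_blur(truth, s))
  names(out) <- sprintf("sigma_%g", sigmas)
  out
}
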