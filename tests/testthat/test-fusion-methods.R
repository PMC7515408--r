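test_that("averaging is the pixel mean, symmetric and idempotent", {
  x <- test_card()
  expect_images_close(fuse_average(x, x), x, tol = 0)
  out <- fuse_average(constant_image(0), constant_image(200))
  expect_true(all(out == 100))
  a <- noise_image(32, 1); b <- noise_image(32, 2)
  expect_equal(pixel_matrix(fuse_average(a, b)),
               pixel_matrix(fuse_average(b, a)))
})

test_that("PCA fusion weights follow the dominant eigenvector", {
  x <- test_card()
  expect_images_close(fuse_pca(x, x), x, tol = 0)
  # high-variance a, uncorrelated low-variance b: weights collapse onto a
  set.seed(21)
  a <- gray_image(matrix(runif(64^2, 0, 255), 64))
  b <- gray_image(matrix(128 + rnorm(64^2, 0, 2), 64))
  out <- fuse_pca(a, b)
  expect_lt(mean(abs(pixel_matrix(out) - pixel_matrix(a))),
            0.05 * mean(abs(pixel_matrix(a) - pixel_matrix(b))))
  expect_error(fuse_pca(constant_image(10), constant_image(90)),
               "degenerate covariance")
})

test_that("Laplacian pyramid keeps the sharper detail on each half", {
  spec <- synth_spec(seed = 12)
  mf <- make_multifocus_pair(spec)
  expect_images_close(fuse_laplacian_pyramid(mf$truth, mf$truth), mf$truth)
  out <- fuse_laplacian_pyramid(mf$a, mf$b)
  left <- mf$mask
  for (half in list(left, !left)) {
    s <- sharpness(out, half)
    expect_gte(s, 0.98 * max(sharpness(mf$a, half), sharpness(mf$b, half)))
  }
  expect_error(fuse_laplacian_pyramid(constant_image(1, 8),
                                      constant_image(1, 8), levels = 4),
               "too small")
})

test_that("contrast pyramid reconstructs and fuses multiplicatively", {
  x <- test_card()
  expect_images_close(fuse_contrast_pyramid(x, x), x)  # round-trip identity
  u <- fuse_contrast_pyramid(constant_image(40, 64), constant_image(80, 64))
  expect_images_close(u, constant_image(60, 64))
  spec <- synth_spec(seed = 13, height = 64, width = 64)
  mf <- make_multifocus_pair(spec)
  expect_images_close(fuse_contrast_pyramid(mf$a, mf$b),
                      fuse_contrast_pyramid(mf$b, mf$a))
})

test_that("block DCT selects the textured block and averages flat ones", {
  x <- test_card()
  expect_images_close(fuse_dct(x, x), x)
  # textured block in a vs flat b of equal mean: a's block is forced
  ap <- matrix(128, 16, 16)
  ap[1:8, 1:8] <- matrix(c(100, 156), 8, 8)
  a <- gray_image(ap)
  b <- constant_image(128, 16)
  out <- fuse_dct(a, b)
  expect_images_close(gray_image(pixel_matrix(out)[1:8, 1:8, drop = FALSE]),
                      gray_image(ap[1:8, 1:8, drop = FALSE]))
  # two constants: their average
  cc <- fuse_dct(constant_image(10, 16), constant_image(30, 16))
  expect_images_close(cc, constant_image(20, 16))
  expect_error(fuse_dct(constant_image(1, 4), constant_image(1, 4)),
               "smaller than DCT block")
})

test_that("guided-filter fusion restores sharpness on multi-focus input", {
  spec <- synth_spec(seed = 14)
  mf <- make_multifocus_pair(spec)
  expect_images_close(fuse_guided_filter(mf$truth, mf$truth), mf$truth)
  out <- fuse_guided_filter(mf$a, mf$b)
  expect_gte(sharpness(out), max(sharpness(mf$a), sharpness(mf$b)))
  expect_error(fuse_guided_filter(mf$a, constant_image(0, 8)),
               "shape mismatch")
})

test_that("all methods are symmetric in their inputs within a gray level", {
  spec <- synth_spec(seed = 15, height = 64, width = 64)
  mf <- make_multifocus_pair(spec)
  for (fn in list(fuse_average, fuse_pca,
                  function(a, b) fuse_laplacian_pyramid(a, b, 3),
                  function(a, b) fuse_contrast_pyramid(a, b, 3),
                  fuse_dct)) {
    expect_images_close(fn(mf$a, mf$b), fn(mf$b, mf$a), tol = 1)
  }
})

test_that("fuse_all returns a labeled fusion_set in the valid range", {
  spec <- synth_spec(seed = 16, height = 64, width = 64)
  mf <- make_multifocus_pair(spec)
  fs <- fuse_all(mf$a, mf$b, levels = 3)
  expect_s3_class(fs, "fusion_set")
  expect_setequal(names(fs$fused), c("average", "pca", "lp", "cp", "dct", "gf"))
  for (f in fs$fused) {
    expect_gte(min(f), 0); expect_lte(max(f), 255)
  }
  expect_error(fusion_set(mf$a, mf$b, list(mf$truth)), "labels")
  expect_error(fusion_set(mf$a, mf$b, list(x = mf$truth, x = mf$truth)),
               "labels")
})
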