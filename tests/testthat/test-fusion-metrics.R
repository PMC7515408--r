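test_that("MI metric doubles the entropy when F copies both sources", {
  x <- test_card()
  r <- metric_mi(x, x, x)
  expect_equal(r$value, 2 * shannon_entropy(marginal_hist(x)))
  expect_identical(r$value, r$component_fa + r$component_fb)

  # a bijective intensity remap preserves MI exactly
  a <- full_range_card()
  b <- gray_image(255 - pixel_matrix(a))
  r2 <- metric_mi(a, b, a)
  expect_equal(r2$value, 2 * shannon_entropy(marginal_hist(a)))
})

test_that("independent noise scores near zero under the information metrics", {
  spec <- synth_spec(seed = 3)
  mf <- make_multifocus_pair(spec)
  f <- noise_image(n = 256L, seed = 99)
  # 64 bins keeps histogram-estimator bias far below the asserted bound
  r <- metric_mi(mf$a, mf$b, f, bins = 64)
  expect_lt(r$value, 0.2)
  expect_lt(metric_tsallis(mf$a, mf$b, f, bins = 64)$value, 0.2)
  expect_lt(metric_nmi(mf$a, mf$b, f, bins = 64)$value, 0.1)
})

test_that("NMI equals 2 on a perfect copy and stays within [0, 2]", {
  x <- test_card()
  expect_lt(abs(metric_nmi(x, x, x)$value - 2), 1e-6)
  expect_error(metric_nmi(x, x, constant_image(7, n = 64)),
               "degenerate entropy")
  spec <- synth_spec(seed = 8, height = 64, width = 64)
  mf <- make_multifocus_pair(spec)
  for (f in list(mf$truth, fuse_average(mf$a, mf$b), noise_image(64))) {
    v <- metric_nmi(mf$a, mf$b, f)$value
    expect_gte(v, 0); expect_lte(v, 2)
  }
})

test_that("Tsallis metric hits the diagonal-joint value and grows toward the source", {
  two <- gray_image(matrix(c(0, 255), 16, 16))
  r <- metric_tsallis(two, two, two, q = 2)
  expect_equal(r$value, 2)
  # value rises as F interpolates from noise toward source a
  a <- test_card(64)
  nz <- noise_image(64, seed = 1)
  vals <- sapply(c(0, 1 / 3, 2 / 3, 1), function(t) {
    f <- gray_image((1 - t) * pixel_matrix(nz) + t * pixel_matrix(a))
    metric_tsallis(a, gray_image(pixel_matrix(a)[, 64:1]), f, bins = 64)$value
  })
  expect_true(all(diff(vals) > 0))
})

test_that("Arimoto metric is symmetric, additive, and Shannon-limited", {
  spec <- synth_spec(seed = 4, height = 64, width = 64)
  mf <- make_multifocus_pair(spec)
  f <- fuse_average(mf$a, mf$b)
  r <- metric_arimoto(mf$a, mf$b, f)
  expect_equal(r$alpha, 1.5)  # protocol default order
  expect_identical(r$value, r$component_fa + r$component_fb)
  r_swap <- metric_arimoto(mf$b, mf$a, f)
  expect_equal(r_swap$value, r$value)
  expect_gte(r$value, 0)

  expect_equal(metric_arimoto(constant_image(), constant_image(),
                              constant_image())$value, 0)
  two <- gray_image(matrix(c(0, 255), 16, 16))
  expect_equal(metric_arimoto(two, two, two, alpha = 2)$value,
               2 * 2 * (sqrt(2) - 1))

  near1 <- metric_arimoto(mf$a, mf$b, f, alpha = 1 + 1e-7)$value
  nats <- metric_mi(mf$a, mf$b, f, base = exp(1))$value
  expect_lt(abs(near1 - nats), 1e-3)
  expect_error(metric_arimoto(mf$a, mf$b, f, alpha = -1), "positive")
  expect_error(metric_arimoto(mf$a, mf$b, constant_image(0, 8)),
               "shape mismatch")
})

test_that("Petrovic metric rewards preserved edges and punishes lost ones", {
  x <- test_card()
  expect_lt(abs(metric_petrovic(x, x, x)$value - 1), 1e-6)
  spec <- synth_spec(seed = 6, height = 64, width = 64)
  mf <- make_multifocus_pair(spec)
  flat <- metric_petrovic(mf$a, mf$b, constant_image(100, 64))$value
  expect_lt(flat, 0.05)
  avg <- metric_petrovic(mf$a, mf$b, fuse_average(mf$a, mf$b))$value
  expect_gt(avg, flat)
  expect_lt(avg, metric_petrovic(mf$a, mf$b, mf$truth)$value)
  for (v in c(flat, avg)) { expect_gte(v, 0); expect_lte(v, 1) }
  # constant everything: no edges exist, vacuously perfect, never NaN
  expect_equal(metric_petrovic(constant_image(), constant_image(),
                               constant_image())$value, 1)
})

test_that("alpha sweep tabulates the metric over the order grid", {
  expect_equal(length(arimoto_alpha_grid()), 10L)
  spec <- synth_spec(seed = 9, height = 64, width = 64)
  mf <- make_multifocus_pair(spec)
  f <- fuse_average(mf$a, mf$b)
  one <- alpha_sweep(mf$a, mf$b, list(avg = f), alphas = 1.5)
  expect_equal(nrow(one), 1L)
  expect_equal(one$value, metric_arimoto(mf$a, mf$b, f)$value)

  dup <- alpha_sweep(mf$a, mf$b, list(x = f, y = f))
  expect_equal(nrow(dup), 20L)
  wide <- reshape(dup, direction = "wide", idvar = "alpha",
                  timevar = "label")
  expect_equal(wide$value.x, wide$value.y)
})
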