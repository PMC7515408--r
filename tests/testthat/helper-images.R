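# Deterministic fixture images built in code.

# full-range structured card: diagonal ramp + checker + bright disc
test_card <- function(n = 64L) {
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  ramp <- (rows + cols - 2) / (2 * (n - 1)) * 200
  checker <- ((rows %/% 4 + cols %/% 4) %% 2) * 40
  disc <- (((rows - n / 3)^2 + (cols - n / 2)^2) <= (n / 6)^2) * 30
  gray_image(ramp + checker + disc)
}

# image holding each 8-bit level equally often (for bijection tests)
full_range_card <- function() {
  gray_image(matrix(rep(0:255, each = 4), nrow = 32))
}

constant_image <- function(value = 128, n = 32L) {
  gray_image(matrix(value, n, n))
}

noise_image <- function(n = 64L, seed = 42L) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  gray_image(matrix(stats::runif(n * n, 0, 255), n, n))
}

expect_images_close <- function(x, y, tol = 1) {
  expect_lte(max(abs(pixel_matrix(as_gray_image(x)) -
                     pixel_matrix(as_gray_image(y)))), tol)
}
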