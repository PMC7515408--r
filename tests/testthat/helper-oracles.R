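# Independent literal-summation oracles: scalar for-loops straight from the
# defining formulas, sharing no code with the package's vectorized paths.

oracle_shannon_entropy <- function(p, base = 2) {
  s <- 0
  for (pi in p) if (pi > 0) s <- s - pi * log(pi, base)
  s
}

oracle_kl <- function(p, q, base = 2) {
  s <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) {
      if (q[i] <= 0) return(Inf)
      s <- s + p[i] * log(p[i] / q[i], base)
    }
  }
  s
}

oracle_shannon_mi <- function(pj, base = 2) {
  px <- numeric(nrow(pj)); py <- numeric(ncol(pj))
  for (i in seq_len(nrow(pj))) for (j in seq_len(ncol(pj))) {
    px[i] <- px[i] + pj[i, j]; py[j] <- py[j] + pj[i, j]
  }
  s <- 0
  for (i in seq_len(nrow(pj))) for (j in seq_len(ncol(pj))) {
    if (pj[i, j] > 0) {
      s <- s + pj[i, j] * log(pj[i, j] / (px[i] * py[j]), base)
    }
  }
  s
}

oracle_arimoto_entropy <- function(p, alpha) {
  s <- 0
  for (pi in p) if (pi > 0) s <- s + pi^alpha
  alpha / (alpha - 1) * (1 - s^(1 / alpha))
}

oracle_arimoto_divergence <- function(p, q, alpha) {
  s <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) {
      if (q[i] <= 0) return(Inf)
      s <- s + p[i]^alpha * q[i]^(1 - alpha)
    }
  }
  alpha / (1 - alpha) * (1 - s^(1 / alpha))
}

oracle_arimoto_mi <- function(pj, alpha) {
  px <- numeric(nrow(pj)); py <- numeric(ncol(pj))
  for (i in seq_len(nrow(pj))) for (j in seq_len(ncol(pj))) {
    px[i] <- px[i] + pj[i, j]; py[j] <- py[j] + pj[i, j]
  }
  s <- 0
  for (i in seq_len(nrow(pj))) for (j in seq_len(ncol(pj))) {
    if (pj[i, j] > 0) s <- s + pj[i, j]^alpha * (px[i] * py[j])^(1 - alpha)
  }
  alpha / (1 - alpha) * (1 - s^(1 / alpha))
}

oracle_tsallis_mi <- function(pj, q) {
  px <- numeric(nrow(pj)); py <- numeric(ncol(pj))
  for (i in seq_len(nrow(pj))) for (j in seq_len(ncol(pj))) {
    px[i] <- px[i] + pj[i, j]; py[j] <- py[j] + pj[i, j]
  }
  s <- 0
  for (i in seq_len(nrow(pj))) for (j in seq_len(ncol(pj))) {
    if (pj[i, j] > 0) s <- s + pj[i, j]^q * (px[i] * py[j])^(1 - q)
  }
  (1 - s) / (1 - q)
}

# all compositions of `total` grid steps into k parts, as probabilities
# (rows); step = 1/total
grid_distributions <- function(k, total = 20L) {
  if (k == 1L) return(matrix(1, 1, 1))
  rec <- function(k, total) {
    if (k == 1L) return(matrix(total, 1, 1))
    out <- list()
    for (first in 0:total) {
      rest <- rec(k - 1L, total - first)
      out[[length(out) + 1L]] <- cbind(first, rest)
    }
    do.call(rbind, out)
  }
  unname(rec(k, total)) / total
}

random_distribution <- function(n) {
  x <- stats::runif(n)
  x / sum(x)
}

random_joint <- function(n) {
  m <- matrix(stats::runif(n * n), n, n)
  m / sum(m)
}
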