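# Entropy, divergence and mutual-information quantities: the Shannon family
# and the one-parameter Arimoto generalization that drives the fusion
# metric, plus the Tsallis mutual information used as a baseline.
#
# Conventions:
#  * Shannon-family quantities take a log base (default 2, bits).
#  * Arimoto/Tsallis quantities are log-free; their alpha -> 1 limits equal
#    the Shannon counterparts in nats.
#  * Sums run over nonzero probabilities only (0 log 0 := 0; 0^negative is
#    never formed).
#  * |alpha - 1| < alpha_tol routes to the exact Shannon-limit code path.

ALPHA_TOL <- 1e-6

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha <= 0) {
    stop("alpha must be a positive number")
  }
  alpha
}

as_prob_vector <- function(p) {
  if (inherits(p, "prob_dist")) as.numeric(p) else as.numeric(prob_dist(p))
}

as_joint_matrix <- function(j) {
  if (!inherits(j, "joint_dist")) j <- joint_dist(j)
  m <- unclass(j)
  attr(m, "n_bins") <- NULL
  m
}

#' Shannon entropy of a discrete distribution
#'
#' `H = -sum p_i log p_i`, with zero-probability bins contributing nothing.
#'
#' @param p A [prob_dist()] or probability vector.
#' @param base Logarithm base; 2 gives bits (default), `exp(1)` nats.
#' @return Entropy, `0 <= H <= log(N, base)`.
#' @examples
#' shannon_entropy(c(0.5, 0.5))         # 1 bit
#' @export
shannon_entropy <- function(p, base = 2) {
  p <- as_prob_vector(p)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Kullback-Leibler divergence
#'
#' `D(p || q) = sum p_i log(p_i / q_i)`. If some `p_i > 0` where `q_i = 0`
#' the divergence is infinite; `+Inf` is returned with a warning.
#'
#' @param p,q [prob_dist()] objects or probability vectors of equal length.
#' @param base Logarithm base (default 2).
#' @return Nonnegative divergence; 0 iff `p == q`.
#' @export
kl_divergence <- function(p, q, base = 2) {
  p <- as_prob_vector(p)
  q <- as_prob_vector(q)
  if (length(p) != length(q)) stop("distributions must have equal length")
  keep <- p > 0
  if (any(q[keep] <= 0)) {
    warning("support violation: p > 0 where q = 0; divergence is infinite")
    return(Inf)
  }
  sum(p[keep] * log(p[keep] / q[keep], base = base))
}

#' Shannon mutual information of a joint distribution
#'
#' The KL divergence between the joint distribution and the product of its
#' marginals.
#'
#' @param j A [joint_dist()] or square probability matrix.
#' @param base Logarithm base (default 2, bits).
#' @return `I >= 0`; 0 for an outer-product (independent) joint.
#' @export
shannon_mi <- function(j, base = 2) {
  pj <- as_joint_matrix(j)
  px <- rowSums(pj)
  py <- colSums(pj)
  nz <- which(pj > 0, arr.ind = TRUE)
  v <- pj[nz]
  sum(v * log(v / (px[nz[, 1]] * py[nz[, 2]]), base = base))
}

#' Arimoto entropy
#'
#' `A_alpha(p) = alpha/(alpha-1) * (1 - (sum p_i^alpha)^(1/alpha))` for
#' `alpha > 0`, `alpha != 1`; as `alpha -> 1` it converges to the Shannon
#' entropy in nats, and within `alpha_tol` of 1 that limit is returned
#' exactly. Nonnegative, concave, permutation-symmetric, and maximized by
#' the uniform distribution at
#' `alpha/(alpha-1) * (1 - N^((1-alpha)/alpha))`.
#'
#' @param p A [prob_dist()] or probability vector.
#' @param alpha Entropic order, `alpha > 0`.
#' @param alpha_tol Half-width of the interval around 1 routed to the
#'   Shannon limit (default 1e-6).
#' @return Entropy in natural units.
#' @examples
#' arimoto_entropy(rep(1 / 4, 4), alpha = 0.5)  # closed form: 3
#' @export
arimoto_entropy <- function(p, alpha, alpha_tol = ALPHA_TOL) {
  check_alpha(alpha)
  p <- as_prob_vector(p)
  if (abs(alpha - 1) < alpha_tol) {
    return(shannon_entropy(p, base = exp(1)))
  }
  s <- sum(p[p > 0]^alpha)
  alpha / (alpha - 1) * (1 - s^(1 / alpha))
}

#' Joint Arimoto entropy of independent variables (pseudo-additivity)
#'
#' For independent variables the joint Arimoto entropy obeys
#' `A(X, Y) = A(X) + A(Y) - (alpha-1)/alpha * A(X) A(Y)`; this evaluates
#' that combination from the two marginal entropies.
#'
#' @param ax,ay Marginal Arimoto entropies of the independent variables.
#' @param alpha Entropic order used for `ax` and `ay`.
#' @return The joint entropy under independence.
#' @export
arimoto_joint_entropy_indep <- function(ax, ay, alpha) {
  check_alpha(alpha)
  ax + ay - (alpha - 1) / alpha * ax * ay
}

#' Arimoto divergence between two distributions
#'
#' The Arimoto analogue of the KL divergence:
#' `D_A(p || q) = alpha/(1-alpha) * (1 - (sum p_i^alpha q_i^(1-alpha))^(1/alpha))`.
#'
#' The `1 - alpha` exponent on `q` is what makes `D_A(p || p) = 0`, keeps
#' the divergence nonnegative, and recovers the KL divergence (nats) as
#' `alpha -> 1`. A variant with exponent `alpha - 1` on `q` — which has
#' none of those properties — can be obtained with `as_printed = TRUE` for
#' auditing; see the package vignette.
#'
#' @param p,q Distributions of equal length; wherever `p_i > 0`, `q_i`
#'   must be positive (else `+Inf` with a warning).
#' @param alpha Order, `alpha > 0`; near 1 the KL limit (nats) is returned.
#' @param as_printed Use the uncorrected `alpha - 1` exponent.
#' @param alpha_tol Shannon-limit routing tolerance.
#' @return Nonnegative divergence (natural units); 0 iff `p == q`.
#' @export
arimoto_divergence <- function(p, q, alpha, as_printed = FALSE,
                               alpha_tol = ALPHA_TOL) {
  check_alpha(alpha)
  p <- as_prob_vector(p)
  q <- as_prob_vector(q)
  if (length(p) != length(q)) stop("distributions must have equal length")
  if (abs(alpha - 1) < alpha_tol) {
    return(kl_divergence(p, q, base = exp(1)))
  }
  keep <- p > 0
  if (any(q[keep] <= 0)) {
    warning("support violation: p > 0 where q = 0; divergence is infinite")
    return(Inf)
  }
  expo <- if (as_printed) alpha - 1 else 1 - alpha
  s <- sum(p[keep]^alpha * q[keep]^expo)
  alpha / (1 - alpha) * (1 - s^(1 / alpha))
}

#' Arimoto mutual information of a joint distribution
#'
#' The Arimoto divergence between the joint distribution and the product of
#' its marginals, summed over the joint's nonzero support. Zero for
#' independent joints, nonnegative with the corrected exponent, and equal
#' to the Shannon mutual information (nats) as `alpha -> 1`.
#'
#' @param j A [joint_dist()] or square probability matrix.
#' @param alpha Order, `alpha > 0`.
#' @param as_printed Use the uncorrected exponent (see
#'   [arimoto_divergence()]).
#' @param alpha_tol Shannon-limit routing tolerance.
#' @return Mutual information in natural units.
#' @examples
#' arimoto_mi(diag(2) / 2, alpha = 2)   # 2 * (sqrt(2) - 1)
#' @export
arimoto_mi <- function(j, alpha, as_printed = FALSE, alpha_tol = ALPHA_TOL) {
  check_alpha(alpha)
  pj <- as_joint_matrix(j)
  if (abs(alpha - 1) < alpha_tol) {
    return(shannon_mi(pj, base = exp(1)))
  }
  px <- rowSums(pj)
  py <- colSums(pj)
  nz <- which(pj > 0, arr.ind = TRUE)
  prod_marg <- px[nz[, 1]] * py[nz[, 2]]
  expo <- if (as_printed) alpha - 1 else 1 - alpha
  s <- sum(pj[nz]^alpha * prod_marg^expo)
  alpha / (1 - alpha) * (1 - s^(1 / alpha))
}

#' Pseudo-additive form of the Arimoto mutual information
#'
#' The joint-entropy combination
#' `A(X) + A(Y) - (alpha-1)/alpha A(X) A(Y) - A(X, Y)`, with `A(X, Y)` the
#' Arimoto entropy of the flattened joint. It vanishes for independent
#' joints but differs from the divergence form [arimoto_mi()] for
#' `alpha != 1`; it is provided as a diagnostic, the fusion metric uses the
#' divergence form.
#'
#' @inheritParams arimoto_mi
#' @return Mutual-information-like quantity in natural units.
#' @export
arimoto_mi_pseudo <- function(j, alpha, alpha_tol = ALPHA_TOL) {
  check_alpha(alpha)
  pj <- as_joint_matrix(j)
  if (abs(alpha - 1) < alpha_tol) {
    return(shannon_mi(pj, base = exp(1)))
  }
  ax <- arimoto_entropy(rowSums(pj), alpha, alpha_tol)
  ay <- arimoto_entropy(colSums(pj), alpha, alpha_tol)
  axy <- arimoto_entropy(as.numeric(pj), alpha, alpha_tol)
  arimoto_joint_entropy_indep(ax, ay, alpha) - axy
}

#' Tsallis mutual information of a joint distribution
#'
#' The Tsallis relative entropy between the joint and the product of its
#' marginals:
#' `I_q = 1/(1-q) * (1 - sum p(x,y)^q (p(x) p(y))^(1-q))` over the joint's
#' nonzero support. Zero for independent joints; Shannon MI (nats) as
#' `q -> 1`.
#'
#' @param j A [joint_dist()] or square probability matrix.
#' @param q Tsallis order, `q > 0`, `q != 1` (near 1 routes to the Shannon
#'   limit).
#' @param alpha_tol Shannon-limit routing tolerance.
#' @return Mutual information in natural units.
#' @export
tsallis_mi <- function(j, q, alpha_tol = ALPHA_TOL) {
  check_alpha(q)
  pj <- as_joint_matrix(j)
  if (abs(q - 1) < alpha_tol) {
    return(shannon_mi(pj, base = exp(1)))
  }
  px <- rowSums(pj)
  py <- colSums(pj)
  nz <- which(pj > 0, arr.ind = TRUE)
  s <- sum(pj[nz]^q * (px[nz[, 1]] * py[nz[, 2]])^(1 - q))
  (1 - s) / (1 - q)
}
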