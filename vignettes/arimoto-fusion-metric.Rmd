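---
title: "Assessing fused images with Arimoto information"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing fused images with Arimoto information}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arifuse)
```

## The problem

Fusing two co-registered grayscale images — a multi-focus pair from one
scene photographed at two focus settings, or a multi-modal pair such as
CT and MR of the same anatomy — should produce an image retaining the
salient content of both. Judging how well that worked is awkward because
no ground-truth fused image exists. No-reference fusion metrics therefore
score the fused image `F` using only its statistical relationship to the
sources `A` and `B`. This package implements such a metric built on the
Arimoto entropy, plus the standard baselines, entirely from joint
gray-level histograms.

## The model

All information quantities are estimated from histograms of 8-bit
intensities. `marginal_hist()` bins pixels into `bins` equal-width bins
over the full `[0, 255]` range (256 by default, plain counting, no
smoothing or partial-volume interpolation); `joint_hist()` counts
co-located intensity pairs. Row and column sums of the joint histogram
reproduce the marginals exactly because all three come from the same
integer counts.

The Arimoto entropy of order $\alpha$ of $p = (p_1,\dots,p_N)$ is

$$A_\alpha(p) = \frac{\alpha}{\alpha-1}\left[1 -
  \Big(\sum_i p_i^\alpha\Big)^{1/\alpha}\right],\qquad \alpha>0,\ \alpha\neq 1.$$

It is nonnegative, concave, permutation-symmetric, maximized by the
uniform distribution at $\frac{\alpha}{\alpha-1}(1-N^{(1-\alpha)/\alpha})$,
pseudo-additive over independent variables
($A(X,Y)=A(X)+A(Y)-\frac{\alpha-1}{\alpha}A(X)A(Y)$), and converges to
the Shannon entropy in nats as $\alpha \to 1$. The property-based test
suite exercises each of these directly.

The matching divergence is

$$D_\alpha(p\,\|\,q) = \frac{\alpha}{1-\alpha}\left[1 -
  \Big(\sum_i p_i^\alpha q_i^{1-\alpha}\Big)^{1/\alpha}\right].$$

**A note on the exponent.** Some statements of this divergence carry
$q_i^{\alpha-1}$ on the marginal term. That form is not a divergence: the
inner sum $\sum p_i^\alpha q_i^{\alpha-1}$ does not equal one at $p = q$,
the quantity can go negative for $\alpha>1$ on dependent joints, and the
$\alpha\to 1$ limit is not the KL divergence. With $q_i^{1-\alpha}$ all
three properties hold, which is what any positive, Shannon-limited
information score requires; `arifuse` uses the corrected exponent and
keeps the other form available behind `as_printed = TRUE` purely for
auditing.

Applying $D_\alpha$ to a joint histogram against the product of its
marginals (over the joint's nonzero support — zero cells are skipped, so
$0^{\text{negative}}$ never arises) yields the generalized mutual
information $I_\alpha$, and the fusion metric is

$$M_\alpha(A,B;F) = I_\alpha(F,A) + I_\alpha(F,B),$$

the total generalized information the fused image shares with its two
sources. The decomposition into the two components is exact by
construction, and the metric is symmetric in $A$ and $B$. A
pseudo-additive joint-entropy form of $I_\alpha$
(`arimoto_mi_pseudo()`) is also provided; it agrees with the divergence
form only at $\alpha = 1$ and serves as a diagnostic — the metric itself
always uses the divergence form.

### Parameters that matter

* **`alpha`** (dimensionless, default **1.5**). Small orders
  ($\le 1.1$) compress differences between mediocre candidates; large
  orders ($\ge 1.9$) over-weight the histogram's heaviest cells and can
  invert mid-rank candidates. Orders around 1.5–1.75 separate fusion
  quality best, hence the 1.5 default; `alpha_sweep()` reproduces this
  behavior on any input over the standard ten-order grid
  $\{0.2, 0.5, 0.9, 1.1, 1.2, 1.5, 1.6, 1.75, 1.9, 2.0\}$.
  Orders within $10^{-6}$ of 1 route to the exact Shannon-limit code
  path (nats); `alpha \le 0` is rejected.
* **`bins`** (default 256). The paper-scale MI magnitudes (≈ 7–9 bits
  for natural 8-bit images) correspond to 256-bin histograms. Note that
  histogram MI carries an upward estimator bias of roughly
  $(B-1)^2/(2N\ln 2)$ bits for $B$ occupied bins and $N$ pixels;
  comparisons between candidates on the same pair are unaffected, but
  absolute "near-zero" statements need either large images or coarser
  bins.
* **`q`** (Tsallis order, default 1.85, the convention of the
  comparison literature) — configurable, same binning.
* **Petrovic constants**: sigmoid gains/slopes/offsets
  $(0.9994, -15, 0.5)$ for gradient strength and $(0.9879, -22, 0.8)$
  for orientation, weighting exponent $L=1$, all exposed through
  `petrovic_constants()`. By default each sigmoid is normalized by its
  value at perfect preservation so that an exact copy of the sources
  scores exactly 1; `normalise = FALSE` restores the raw sigmoids
  (which top out near 0.975).

### Numerical choices and degenerate inputs

Sums skip zero-probability cells. Constant images are legal everywhere
except `metric_nmi()` (zero entropy makes the normalization undefined;
a "degenerate entropy" error is raised) and `fuse_pca()` (a zero
covariance matrix has no principal direction). The Petrovic metric
defines two all-constant sources as vacuously perfect (no edges to
lose, value 1) rather than returning NaN. Ranking ties are broken by
input order and flagged in a `tied` column, never silently. Probability
vectors are renormalized exactly after counting so histogram totals hit
1 to machine precision.

## The fusion fixtures

Six classical algorithms generate candidates of genuinely different
quality; they exist to exercise the metrics, not to match any specific
third-party implementation. Averaging is the pixel mean. PCA weights the
images by the principal eigenvector of their 2×2 covariance (nonnegative
weights summing to one; mixed-sign eigenvectors fall back to
variance-proportional weights). The Laplacian pyramid (4 levels, 5-tap
binomial kernel 1-4-6-4-1/16, reflective borders) fuses detail by
max-absolute selection and averages the coarsest base; the contrast
pyramid does the same on ratio-of-lowpass coefficients (offset of one
gray level keeps ratios finite, selection by $|c-1|$, multiplicative
reconstruction). Block-DCT (8×8, replicate-padded) keeps the tile with
higher AC energy and averages DC terms. Guided-filter fusion splits each
image into a box-mean base layer (radius 15) and detail residual, takes
Gaussian-smoothed absolute-Laplacian saliency (σ = 5), and refines the
binary saliency-argmax weight maps by guided filtering with the source
as guide — radius 31 / ε 10⁻³ for base weights, radius 7 / ε 10⁻⁶ for
detail weights on the unit intensity scale — before normalized blending.
All outputs are clipped to the valid range; every method returns the
input (within one gray level of reconstruction round-off) when both
sources are identical.

## What the synthetic generator emulates — and what it does not

`make_multifocus_pair()` renders a procedural latent scene (smooth random
field + sinusoidal gratings + random shapes, rescaled to full 8-bit
range) and defocuses complementary regions of it with a Gaussian blur of
`blur_sigma` pixels (default 3, a visually obvious defocus at 256×256,
the benchmark image size). `make_multimodal_pair()` re-renders the
latent scene through two monotone gamma maps (1 and `modality_gamma`,
default 2) and composites independent exclusive content over
`exclusive_fraction` (default 0.25) of each modality's pixels — the
CT/MR situation of shared anatomy plus sensor-specific tissue. Both are
bit-reproducible from a seed and never touch the caller's RNG stream.

This reproduces the *statistical* structure the metrics rely on —
complementary sharpness, monotone cross-modal intensity relations,
partially exclusive content — but not the optics of real defocus
(depth-dependent point-spread functions), sensor noise, registration
error, or anatomical texture. Passing tests therefore demonstrate the
metric's behavior under controlled informational conditions, not its
agreement with human observers on clinical data.

One structural subtlety is worth knowing: on a pair defocused with
$\sigma = 3$, the ladder rung $F = \mathrm{blur}(\text{truth}, 3)$
coincides *exactly* with source $a$ on one half of the image and with
$b$ on the other, so $M_\alpha$ correctly reports near-maximal shared
information for it. Blur ladders used to probe monotonicity are
therefore built from rungs (0, 1, 2, 4, 6, 9 px) that do not coincide
with the acquisition blur.

## Design decisions taken where the protocol was open

* The divergence-form $I_\alpha$ (not the pseudo-additive form) drives
  $M_\alpha$: only it inherits nonnegativity from the corrected
  divergence.
* The DCT selection rule is AC-energy winner-take-all with DC averaging
  — the simplest rule consistent with "means and variances" block
  fusion.
* Rank agreement against a reference ordering uses Kendall's $\tau$
  (with Spearman's $\rho$ alongside); $\tau = 1$ iff the orders agree
  exactly.
* The quality reference for fixture-ranking checks is the
  full-reference RMSE against the latent sharp scene, computed at run
  time — available here precisely because the generator knows its
  ground truth.
* Problem sizes in the test suite: property sweeps use ≥ 100 random
  distributions per order with $N$ up to 256; literal-summation oracle
  checks enumerate the full 0.05-step probability grid for $N \le 3$
  (all pairs) and $N = 4$ (entropies, joints, and a spread of
  full-support divergence partners); image-level checks run at 256×256,
  the benchmark size.

## Known limitations

Histogram MI needs enough pixels per occupied bin; below ~64×64 with
256 bins the estimator bias dominates. The metric is intensity-based
and position-blind: a fused image that permuted pixels consistently
with the sources would score identically, so it cannot detect geometric
artifacts — that is what edge-based measures like Q^AB/F complement.
All inputs are assumed co-registered; no registration is attempted.
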