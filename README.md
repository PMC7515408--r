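# arifuse

Objective, **no-reference quality assessment of fused images** in R.

Image fusion combines two co-registered single-channel images — a
multi-focus pair with complementary in-focus regions, or a multi-modal
pair such as CT and MR of the same anatomy — into one image that should
retain the salient content of both. Because a ground-truth "ideal" fused
image rarely exists, fusion quality must be judged from the fused image
`F` and its sources `A`, `B` alone. `arifuse` is for researchers and
engineers who need such scores: it implements an information-theoretic
metric built on **Arimoto entropy**, the baselines it is usually compared
against, six classical fusion algorithms to generate test stimuli, and a
deterministic synthetic generator of multi-focus and multi-modal pairs so
the whole evaluation protocol runs without any external dataset.

## The metric

The Arimoto entropy of order α > 0 (α ≠ 1) of a distribution
p = (p₁, …, p_N) is

    A_α(p) = α/(α−1) · [ 1 − (Σᵢ pᵢ^α)^{1/α} ]

a concave, nonnegative, permutation-symmetric generalization of Shannon
entropy (recovered in nats as α → 1). The associated divergence,

    D_α(p‖q) = α/(1−α) · [ 1 − (Σᵢ pᵢ^α qᵢ^{1−α})^{1/α} ]

applied to the joint gray-level histogram of two images versus the product
of its marginals gives a generalized mutual information I_α. The fusion
metric is the total generalized information the fused image carries about
both sources:

    M_α(A, B; F) = I_α(F, A) + I_α(F, B)

Larger is better; the default operating order is **α = 1.5**. Baselines:
Shannon MI (bits), normalized MI, the Tsallis-divergence metric, and the
Petrovic edge-preservation measure Q^AB/F. Fusion fixtures: pixel
averaging, PCA weighting, Laplacian and contrast pyramids, 8×8 block-DCT
selection, and guided-filter two-scale fusion.

## Worked example

```r
library(arifuse)

spec <- synth_spec(seed = 0)            # 256 x 256, defocus sigma = 3 px
pair <- make_multifocus_pair(spec)      # a, b, and the latent sharp truth
fs   <- fuse_all(pair$a, pair$b)        # six classical fusion candidates

metric_arimoto(pair$a, pair$b, fs$fused$gf)
#> arimoto (alpha = 1.5): 14.1263 nats
#>   I(F,A) = 7.27729   I(F,B) = 6.84904

rank_fusions(pair$a, pair$b, fs$fused, metrics = "arimoto")$arimoto
#> Ranking under metric 'arimoto'
#>    label     value rank  tied
#>       gf 14.126332    1 FALSE
#>       cp 10.300790    2 FALSE
#>       lp 10.299576    3 FALSE
#>      pca  9.432640    4 FALSE
#>      dct  9.381380    5 FALSE
#>  average  9.259663    6 FALSE
```

The guided-filter fusion, which restores sharp detail from both sources,
scores highest; plain averaging, which dilutes detail, scores lowest —
the ordering a human judge gives these candidates. `alpha_sweep()`
tabulates M_α over the standard ten-order grid (0.2 … 2.0) to visualize
how order choice affects separation.

A command-line tool wrapping these functions ships in
`inst/cli/arifuse.R` with subcommands `score`, `rank`, `sweep`, `fuse`
and `simulate`; run it with `Rscript` and `--help`-style usage in the
file header.

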