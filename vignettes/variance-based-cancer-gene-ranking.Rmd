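---
title: "Variance-based ranking of cancer genes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance-based ranking of cancer genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetrank)
```

## The scientific model

`hetrank` rests on one generative idea about tumor biology: tumors are
heterogeneous at the gene level. A driver gene is not dysregulated in every
tumor — each tumor uses its own subset of drivers — so a cancer gene is
extreme in only a fraction of tumor samples. Two consequences follow for
bulk expression data with an adjacent-normal (AN) and a tumor (T) group:

1. the tumor-group **mean** of a cancer gene barely moves (the extreme
   values are diluted by the unaffected tumors), so mean-comparison
   statistics (fold change, the t test) lose power;
2. the tumor-group **standard deviation** SD(T) is inflated by the mixture,
   so interindividual variation becomes the informative statistic.

The package operationalizes this as a predictor-evaluation ("reverse
genomics") pipeline: take genes with known cancer-gene labels, compute six
per-gene statistics — m(AN), m(T), SD(AN), SD(T), fold change, and
−log10 p of the pooled two-sample t test — and measure how well each
statistic separates labeled from unlabeled genes (Mann–Whitney Z) and
concentrates labels at the top of its ranking (enrichment factor, the
labeled share of the top 5% divided by 5%).

The pipeline assumes: log2-scale, roughly Gaussian within-group expression;
independent samples (no pairing of AN and T from the same patient is
exploited); one rankable unit per matrix row (rows may be probes or genes —
label matching is by exact row identifier, and many-probes-per-gene
aggregation is left to the user); and a label list that is a noisy but
unbiased marker of true cancer involvement.

## The two simulation models

The simulation study contrasts two generative models that produce the *same*
tumor-group mean shift `s`:

* **Shifting means** — every tumor value of a cancer gene is drawn from
  `N(7 + s, 0.6)`. The mean moves; the variance does not.
* **Outliers** — only `n_out` of the `n_t` tumors are shifted, each by `d`,
  with the mean-matching constraint `n_out · d / n_t = s`. The sample
  variance is inflated to `σ² + d² · n_out(n_t − n_out) / (n_t(n_t − 1))`
  in expectation.

Because the number/magnitude split `(n_out, d)` is underdetermined by the
mean constraint, the package fixes a target magnitude `d_target = 3.5` log2
units (about 5.8 baseline SDs — an "extreme dysregulation" on an
expression scale where the baseline SD is 0.6) and sets
`n_out = max(1, round(n_t · s / d_target))`, then `d = n_t · s / n_out`
exactly. At the default `n_t = 20` this gives `(n_out, d)` = (1, 1.4),
(2, 3.5), (4, 3.5) for s = 0.07, 0.35, 0.7. Shifts are upward by default;
`two_sided = TRUE` draws a fair-coin direction per gene.

Identification efficacy is scored as **recovery at k**: rank genes by SD(T)
or by −log10 p, take the top `k = n_cancer` (the standard
recovery-at-k convention; the cutoff is exposed as `top_n`), and report the
fraction of true cancer genes recovered. Recovery is invariant under any
strictly increasing transform of the statistic, which is also why reporting
fold change as `|Δlog2|` or `2^|Δlog2|` is immaterial for every ranking
result — the package reports both.

## Synthetic cohorts: what they emulate and what they do not

`generate_null_cohort()` and `generate_heterogeneous_cohort()` emulate the
statistical skeleton the analysis relies on: per-gene baseline `N(7, 0.6)`
on the log2 scale (typical of normalized microarray data), two sample
groups, and — in the heterogeneous case — cancer genes dysregulated by
±`outlier_shift` in each tumor independently with probability
`outlier_fraction`, direction fixed per gene. The per-tumor Bernoulli
mechanism (rather than a fixed outlier count) is the simplest mechanism
consistent with "different tumors use different drivers". The
`an_sd_inflation` knob (default 1, i.e. off) lets cancer genes vary more in
adjacent normal tissue too, a pattern seen in real tumor cohorts.

Deliberately **not** modeled: gene–gene correlation, array batch effects,
probe-level noise, copy-number covariates, non-Gaussian tails, and
paired AN/T structure. Passing tests on these cohorts therefore shows that
the statistics behave as designed under the stated mechanism — not that the
method is robust to everything real microarray data can do. The study
conditions used throughout the tests are 1000 genes (50 cancer), 20 + 20
samples, `outlier_fraction = 0.2`, `outlier_shift = 3.0`; null calibrations
use 10,000 genes with 500 random labels over 200 seeded replicates, which
puts the Monte-Carlo error on a mean enrichment factor near 0.01.

## Numerical and procedural choices

* **Student t**: equal-variance (pooled) form, two-sided,
  df = n₁ + n₂ − 2 — not Welch. −LOG is base 10. The p-value is computed on
  the log scale (`pt(..., log.p = TRUE)`) so extreme t statistics do not
  underflow, and −log10 p is capped at 300; a zero-pooled-variance gene
  gets 0 when the means are equal and the cap when they differ, keeping
  every gene rankable.
* **Mann–Whitney**: U for the first sample under the rank-sum convention
  (`U = R_a − n_a(n_a+1)/2`, ties counting one half, so
  `U(a,b) + U(b,a) = n_a n_b`), normal approximation with tie-corrected
  variance and *no* continuity correction ("Z-adjusted" style); all-tied
  input returns Z = 0, p = 1.
* **Ranking and top-k**: descending, stable radix order (ties keep input
  order, never pulling extra genes across the `k = ceiling(0.05 n)` cutoff).
* **Outlier band**: `m(N) ± 4·SD(N)` from the AN samples of the same
  dataset (sample estimates, n−1 SD); the inequalities are strict, so a
  value exactly on the edge is not an outlier. SD(N) = 0 genes cannot
  define a band and are flagged degenerate and excluded from rate
  comparisons. Matched controls are the nearest non-cancer genes above and
  below each cancer gene in the −log10 p ordering (two from one side at a
  list boundary); the pooled control set is de-duplicated.
* **Stepwise logistic**: forward-only likelihood-ratio selection, entry at
  p < 0.05 on a 1-df chi-square, no removal step — the smallest faithful
  reading of "stepwise-forward". Fits are maximum likelihood via
  iteratively reweighted least squares (convergence when the deviance
  change is below 1e−8, at most 100 iterations); non-convergence is warned
  about, never silently accepted. Quasi-separation (fitted probabilities
  pinned to 0/1, or runaway coefficients) is flagged and reported
  coefficients are capped at ±30; the LR statistics that drive selection
  remain finite and unaffected. Predictors enter on their natural scale —
  z-scoring changes coefficients but provably not the selection path or LR
  statistics (a property the tests check).
  One calibration subtlety is worth stating: the 5% entry threshold is a
  *per-candidate* type-I level. With six (correlated) candidates the
  chance that *no* predictor enters on pure noise is at most
  `(1 − 0.05)⁶ ≈ 0.74` under independence, not 95%; an empty selected set
  on null data is the majority outcome, not a 95% guarantee.
* **Degenerate limits**: `outlier_fraction = 0` (or a zero shift) collapses
  the heterogeneous generator to the null cohort; `s = 0` does the same in
  both simulation models, where both statistics recover at the chance level
  `n_cancer / n_genes`.
* **Reproducibility**: every stochastic entry point takes a seed and pins
  the RNG kind (Mersenne-Twister / inversion / rejection), restoring the
  caller's RNG state afterwards, so a fixed seed is bit-reproducible across
  platforms. The pipeline derives one stream per stage from its master seed
  by fixed offsets, so adding a stage never perturbs another stage's draws,
  and records the seed in every report header.

## Limitations

* The enrichment factor depends on the label list; incomplete or biased
  catalogs of known cancer genes shift EF for every predictor.
* SD(T) rewards *any* source of tumor-side variance — technical artifacts,
  sample-quality gradients and batch effects inflate it just as biology
  does; the raw→log2→normalized robustness check (`kendall_tau` on per-gene
  variances) mitigates but does not remove this.
* The outlier band presumes approximately Gaussian AN expression; heavy
  tails in normal tissue produce spurious outliers (no robust median/MAD
  banding is provided).
* With few tumors the SD(T) estimate is noisy; `subsample_robustness()`
  quantifies how often the association survives when only a handful of
  tumors (default 9, 20 resamplings) is available.
* Homogeneous cancers — where most tumors share the same drivers — are the
  shifting-means regime, and there mean-based statistics are the right
  tool; the package's claim is comparative, not absolute.
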