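# hetrank

Ranking cancer genes by interindividual expression variation in tumors.

## The problem

Most expression-based searches for cancer genes compare *mean* expression
between tumors and normal tissue. But tumors are heterogeneous at the gene
level: different tumors are driven by different genes, so a driver gene is
extremely up- or down-regulated in only a fraction of tumors. Averaging over
tumors then washes the signal out of the mean while leaving a strong imprint
on the *between-tumor spread*. `hetrank` implements the resulting "reverse
genomics" analysis: given a gene-by-sample expression matrix with adjacent
normal (AN) and tumor (T) samples and a list of known cancer genes, it asks
which per-gene statistics best predict cancer-gene status.

Six per-gene predictors are computed on log2 expression:

- **m(AN)**, **m(T)** — group means;
- **SD(AN)**, **SD(T)** — group standard deviations (n−1 denominator);
- **FC** — fold change `2^|m(T) − m(AN)|` (reported with `log_fc = |Δ|`);
- **−LOG(P)** — `−log10 p` of the pooled two-sample Student t test
  (df = n₁ + n₂ − 2).

Each predictor is evaluated by (i) a Mann–Whitney U test (tie-corrected
normal approximation, Z-adjusted) of labeled cancer genes vs all other
genes, and (ii) the **enrichment factor** of the ranked list,
`EF = P / 0.05`, where `P` is the proportion of known cancer genes among the
top 5% of genes; `EF = 1` means no better than random selection. The package
also calls per-gene tumor **outliers** (values outside
`m(N) ± 4·SD(N)`, estimated from AN samples) and compares outlier rates of
cancer genes against −log10(p)-matched control genes; runs a **simulation
study** contrasting a shifting-means model (`N(7 + s, 0.6)` in all tumors)
with a mean-matched outliers model (shift `d` in `n_out` tumors with
`n_out·d/n_t = s`); and combines predictors by **stepwise-forward
likelihood-ratio logistic regression** with cancer-gene status as outcome.
Synthetic cohort generators (baseline `N(7, 0.6)` on the log2 scale) make
everything testable without external data.

## Worked example

```r
library(hetrank)

coh <- generate_heterogeneous_cohort(cohort_config(seed = 1))
tab <- compute_predictor_table(coh$dataset)
predictor_comparison(tab, coh$labels)
#> Predictor comparison, cancer vs other genes (Mann-Whitney, top-5% EF)
#>  predictor mean_cancer mean_other  mw_u     mw_z      mw_p rank top_prop   ef
#>       sd_t      1.3090     0.5961 47020 11.69000 1.397e-31    1     0.94 18.8
#>         fc      1.5410     1.1100 44250 10.30000 7.108e-25    2     0.64 12.8
#>    neglogp      1.1720     0.4132 40280  8.30700 9.836e-17    3     0.36  7.2
#>        m_t      7.1510     7.0010 28560  2.41700 1.563e-02    4     0.50 10.0
#>       m_an      6.9770     6.9980 21510 -1.12400 2.611e-01    5     0.06  1.2
#>      sd_an      0.5908     0.5932 23900  0.07284 9.419e-01    6     0.04  0.8
```

The cohort has 1000 genes (50 labeled cancer genes), 20 AN + 20 T samples;
each cancer gene is shifted by ±3 log2 units in each tumor independently
with probability 0.2. SD(T) ranks first: 94% of its top-5% list are true
cancer genes (EF 18.8), well ahead of fold change and the t statistic, while
the mean- and AN-based predictors are near chance. The stepwise logistic
combination picks the same winner:

```r
stepwise_forward_lr(tab, coh$labels)
#> stepwise-forward LR logistic model (1000 genes, 50 cancer; entry p < 0.05)
#>  predictor lr_chi2  p_entry log_likelihood
#>       sd_t  358.34 6.47e-80        -19.345
#>    neglogp    4.05 4.42e-02        -17.320
```

and the 4-SD outlier analysis shows cancer genes out-lying their
differential-expression-matched controls (15.3% ± 1.2 vs 0.5% ± 0.2 of
tumors; MW Z = 9.7):

```r
rep <- call_outliers(coh$dataset)
compare_outlier_rates(rep, coh$labels, matched_controls(tab, coh$labels))
```

`run_simulation_experiment(sim_config(seed = 1))` reproduces the
model-contrast experiment (recovery of the 50 true cancer genes in the top
50 by SD(T) vs −LOG(P), across s ∈ {0.07, 0.35, 0.7}), and
`run_pipeline()` orchestrates the whole analysis on real TSV inputs or a
synthetic cohort, writing TSV reports with a provenance header. A thin
command-line wrapper lives at `inst/scripts/hetrank.R`
(`simulate-cohort`, `predictors`, `enrich`, `outliers`, `stepwise`,
`simulate`, `run`).

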