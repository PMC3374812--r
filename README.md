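# amplimark

Supervised outlier-expression analysis for inferring chromosomal
**amplicons** associated with early relapse in ER-positive breast cancer
treated with endocrine therapy — and, more generally, for any cohort where
a copy-number event drives coordinated over-expression of neighbouring
genes in a subset of tumours.

The package is aimed at computational biologists working with bulk
expression cohorts (genes × samples, multiple batches/platforms) plus
clinical follow-up. It implements the full chain from normalized
expression tables to per-sample amplicon calls and survival
stratification, together with a synthetic-cohort generator that makes
every stage testable without external data.

## The method

For gene *g* in batch *b*, expression is COPA-transformed with robust
per-batch statistics:

    x'[g, s] = (x[g, s] − median_b(x[g, ·])) / MAD_b(x[g, ·])

with the raw MAD (no 1.4826 factor). Per gene, samples outside the 10%/90%
quantile cutoffs (type-7 interpolation, strict inequality) become entries
of binary outlier matrices **B₁** (high) and **B₂** (low); genes with
fewer than 10 outliers are discarded as uninformative. Each remaining
gene's outlier class is compared with its normal class by a log-rank test
(screen at p < 0.05; hazard ratio from univariate Cox with Efron ties).

Screened genes are correlated by the **phi coefficient**
φ = (n₁₁n₀₀ − n₁₀n₀₁)/√(r₁r₀c₁c₀) — the Pearson correlation of binary
outlier profiles — thresholded at τ (default 0.30), pruned to a stable
set by iteratively removing minimum-degree genes, and clustered as the
connected components of the thresholded graph (PCA projections of the
profiles are reported for visualisation). Poor-prognosis cluster genes
are then tested for positional clustering with a sliding window of 25
genes at a pace of 5 along each chromosome, using the one-sided Fisher
exact (hypergeometric) test with Benjamini–Hochberg control at FDR < 5%.
Overlapping significant windows merge into amplicon definitions; a sample
*carries* an amplicon when ≥ 50% of its marker genes are high outliers in
that sample. Carriers are compared with amplicon-free samples by
Kaplan–Meier/log-rank and Cox models.

Two clinical companions are included: a relative Oncotype-Dx-style
recurrence score (per-batch z-scores, group means, published weights) and
FISH spot-count classification (amplified > 4, borderline 2–4, not
amplified < 2 spots/cell over 20 nuclei; presence cutoffs 3.5/4.0/2.8 per
region) with an exhaustive survival-optimised threshold search.

## Worked example

```r
library(amplimark)
set.seed(1)

# a synthetic 3-batch cohort with two planted 25-gene amplicons
co <- simulate_cohort(sim_config(), seed = 1)
pl <- run_amplicon_pipeline(co$expression, co$annotation, co$clinical)
tidy(pl)
#> # A tibble: 2 × 8
#>   name   chrom start_idx end_idx span_start span_end n_markers    q_min
#>   <chr>  <chr>     <int>   <int>      <dbl>    <dbl>     <int>    <dbl>
#> 1 1q2-q3 chr1         31      95    4600000  7550000        26 2.85e-38
#> 2 2q4-q5 chr2         81     145    9500000 12550000        25 1.82e-35

glance(pl)$any_amplicon_hr
#> [1] 2.852694
pl$outcomes[, c("amplicon", "n_carrier", "hazard_ratio", "p_value")]
#> 1q2-q3         20  2.83  5.69e-06
#> 2q4-q5         18  2.90  1.39e-05
#> any_amplicon   38  2.85  2.76e-09
```

Both defined regions cover the planted spans (chr1 genes 51–75, chr2
genes 101–125), nothing else is reported, and carriers of any amplicon
relapse markedly earlier (HR ≈ 2.9 against the planted per-amplicon
hazard ratio of 4 — attenuated because quantile-based calling can flag at
most ~10% of samples per gene, so only the most strongly amplified
carriers are called; see the methods vignette). Amplicon-free samples
stay close to their baseline survival.

Individual stages are exported too: `robust_scale()`, `call_outliers()`,
`outlier_survival_screen()`, `phi_matrix()`, `prune_correlation_graph()`,
`pca_clusters()`, `make_windows()`, `define_amplicons()`,
`call_amplicons_per_sample()`, `stratified_outcome()`,
`relative_odx_score()`, `classify_fish()`, `optimize_fish_thresholds()`.
Results are tibbles; fitted objects support `tidy()`/`glance()`; KM
curves and cluster sets have `autoplot()` methods.

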