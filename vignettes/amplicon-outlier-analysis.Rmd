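---
title: "Outlier-expression inference of prognostic amplicons: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Outlier-expression inference of prognostic amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amplimark)
```

## The problem and the model

A minority of ER-positive breast cancers relapse early despite endocrine
therapy. One recurring mechanism is focal chromosomal amplification: a
tumour that carries extra copies of a region (canonically 17q12/HER2,
but also 8p11.2, 8q24.3 and the 17q21.33–q25.1 stretch) over-expresses
the genes residing there. In a cohort of expression profiles this leaves
a characteristic signature — a *contiguous run* of genes whose expression
is extreme ("outlier") in *the same subset* of samples, and whose outlier
status predicts relapse.

amplimark operationalises that signature in five stages:

1. **Robust scaling.** Per gene and per batch,
   `x' = (x − median) / MAD`, with the raw MAD (no Gaussian consistency
   factor). Scaling within batch is essential: the sub-cohorts come from
   different platforms and sites, and pooled scaling would convert batch
   shifts into spurious outliers. The COPA-style median/MAD pair is
   preferred to mean/SD because an amplified minority inflates the mean
   and SD but barely moves the median and MAD.
2. **Quantile outlier calling.** Per gene, values strictly beyond the
   0.10/0.90 quantiles (type-7 interpolated order statistics) are low/high
   outliers, giving binary matrices B₁/B₂. Genes with fewer than 10
   outliers across the cohort are uninformative for class comparison and
   are dropped.
3. **Survival screen.** Per gene and direction, outlier class vs normal
   class by log-rank test; genes with p < 0.05 are retained with a
   univariate Cox hazard ratio on the outlier indicator. The screen is
   deliberately per-direction: high and low outliers carry different
   biology (amplification vs loss/silencing).
4. **Profile clustering.** Retained genes are correlated by the phi
   coefficient (Pearson on binary profiles), thresholded at τ, pruned to
   a stable set, and clustered as connected components; PCA projections
   of the profiles (genes as observations, mean-centred samples as
   variables) visualise the separation. Clusters inherit a prognosis
   label from the majority HR direction of their members.
5. **Positional enrichment and calling.** Poor-prognosis cluster genes
   are tested against sliding windows (25 genes wide, pace 5) along each
   chromosome by the one-sided hypergeometric (Fisher exact) test with
   genome-wide BH adjustment at FDR < 5%. Overlapping significant windows
   merge into amplicon definitions; a sample carries an amplicon when at
   least 50% of its marker genes are high outliers. Carriers are compared
   with amplicon-free samples (not merely non-carriers of that amplicon)
   by KM/log-rank and Cox.

The two clinical companions — the relative recurrence score and FISH
classification — are described below with their parameters.

## Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `q_low`, `q_high` | 0.10 / 0.90 | quantile | Outlier cutoffs; region identity on the bundled cohort is stable to ±0.05 (tested). |
| `min_outliers` | 10 | samples | Informativeness floor. With per-gene quantile cutoffs roughly 10% of samples are flagged per gene, so at cohort sizes ≥ 100 the filter binds only for degenerate genes; it matters for small cohorts and for the pooled scope. |
| `quantile_scope` | `per_batch` | — | Cutoffs per gene within batch, matching per-batch scaling. A `pooled` mode exists because cutoffs "across samples" after concatenation is an equally defensible reading. |
| `alpha` | 0.05 | p | Log-rank screen threshold, two-sided, each direction tested separately. |
| `tau` | 0.30 | phi | Graph threshold for pruning/clustering. A calibration default: random 30-of-300 binary profiles have phi SD ≈ 0.06, so 0.30 is ≈ 5 SD and random edges are rare, while planted co-amplified profiles correlate far above it. |
| `min_degree` | 1 | edges | Pruning floor; isolated genes are removed. |
| `width`, `pace` | 25 / 5 | genes | Sliding-window geometry; the final window per chromosome anchors to the end so every gene is covered. |
| `fdr` | 0.05 | q | BH level, one genome-wide family per run. |
| marker fraction | 0.5 | — | Per-sample call rule (≥ 50% of markers flagged high). |
| FISH tri-class | >4 / [2,4] / <2 | spots/cell | 20-cell averages; boundary values are borderline. |
| FISH presence | 3.5 / 4.0 / 2.8 | spots/cell | Per-region cutoffs (8p11.2 / 17q22 probe / 8q24.3); survival-optimised in the source assay, hence in-sample — `optimize_fish_thresholds()` reports its full grid trace for the same reason. |
| RS cutoff | 0 | score | Relative recurrence scores are per-batch centred; >0 is "high". |

## The recurrence score

The exact combination formula of the original 21-gene assay is not
reproducible from array data (it is defined on scaled RT-PCR units), so
the package computes the standard *relative* analogue: each panel gene is
z-normalised per batch, groups (HER2, hormonal/ER, proliferation,
invasion) are averaged, and the final score is the weighted sum using the
published group weights of Paik et al. (2004) — shipped as an editable
YAML file and clearly reference-derived. ER, PGR, BCL2 and SCUBE2 enter
as one hormonal group (they are listed together as hormonal markers;
grouping keeps the score's orientation interpretable). The score is
invariant to per-batch affine rescaling and centred near zero per batch;
only its relative ordering and sign are meaningful.

## The synthetic cohort generator

`simulate_cohort()` emulates the features of a multi-site tamoxifen-era
expression cohort that the method relies on:

- **Heavy-tailed background**: t-distributed noise (df = 5 by default)
  with per-batch location/scale offsets, so ~10% of samples per gene are
  flagged even without signal — outlier calling must discriminate signal
  from these background tails, not from Gaussian noise.
- **Planted amplicons**: contiguous gene spans; each carrier (prevalence
  0.25 per amplicon by default) receives a shift of δ = 4 background-MAD
  units on *all* span genes, multiplied by a per-carrier dosage drawn
  from U(0.7, 1.3) and shared across the span — amplification is a
  per-sample copy-number event, so marker over-expression co-occurs
  within a sample rather than independently per gene.
- **A diffuse proliferation set**: 50 "cell-cycle" genes scattered across
  chromosomes, each elevated with probability 0.6 in any carrier sample.
  They pass the survival screen but must *not* yield regions — they are
  the negative control for the positional stage.
- **Survival**: exponential event times with hazard
  `0.03/yr × Π HR^carried`, HR = 4 per amplicon; independent uniform
  censoring whose horizon is solved so ~30% of samples are censored.
- **FISH counts**: carriers draw mean spot counts one unit above the
  region's presence cutoff plus Gaussian noise; non-carriers sit near the
  diploid 2.0; occasional no-signal dropouts.

Default sizes (2000 genes over 10 chromosomes, 3 batches of 100, two
25-gene amplicons) keep a full pipeline run at a few seconds and the
100-replicate null study at a few minutes on one CPU.

What the generator does **not** emulate: probe-level noise, correlated
background (co-expression networks), copy-number *loss*, non-proportional
hazards, and informative censoring. Passing tests therefore demonstrate
correctness of the machinery and recoverability under the stated
generative model, not clinical performance on real cohorts.

## Numerical choices, ties and degenerate inputs

- Quantiles use type-7 linear interpolation, fixed and documented because
  outlier counts depend on the estimator; outlier comparisons are strict,
  so constant genes produce no outliers.
- A gene with MAD = 0 in a batch is flagged degenerate and excluded from
  calling in that batch; genes missing in > 20% of any batch's samples
  are dropped with a warning; medians and quantiles otherwise use
  available values.
- Probe collapsing keeps the probe with the highest median; ties break to
  the lexicographically smallest probe id, making the result order-independent.
- Pruning removes one gene at a time (the minimum-degree gene, ties by
  gene id) and recomputes degrees, so the stable set is independent of
  input order.
- Merging batches intersects gene sets; sample-id collisions across
  batches are errors, never silently renamed.
- Coordinates are 1-based inclusive throughout; BED exports convert to
  0-based half-open.
- The log-rank screen uses an in-package vectorised Mantel–Cox statistic
  (exact agreement with `survival::survdiff` is asserted in the tests);
  single wrapped tests delegate to `survival`. Cox models use Efron tie
  handling since follow-up times are tied after rounding in real tables.
- FISH threshold optimisation breaks ties toward *larger* cutoffs —
  the conservative choice, calling fewer samples amplified.
- Clinical covariates may be missing; models run complete-case with a
  reported count. Nothing is imputed.

## Design choices where the design was open

- **Pruning rule.** The stable-set criterion is implemented as: binarise
  the phi matrix at τ, repeatedly drop the minimum-degree gene while its
  degree is below `min_degree`. This is the simplest rule consistent with
  "iteratively removing row *i* and column *i* until the reduced matrix
  stops changing", and both knobs are exposed.
- **Cluster identification.** Visual circling of PCA groups is replaced
  by connected components of the thresholded phi graph, with PCA retained
  for reporting; components and the visual groups coincide whenever
  between-cluster phi < τ < within-cluster phi.
- **Definitions vs calls.** Amplicon *definitions* come from window
  enrichment of cluster genes; per-*sample* presence uses the explicit
  ≥ 50%-of-markers rule. Window-level per-sample marking would conflate
  the two resolutions.
- **Enrichment universe.** All genes surviving batch intersection — not
  only screened genes — because the window test asks whether cluster
  genes are positionally concentrated relative to the assayed genome.
- **Per-gene HR.** Computed by univariate Cox on the outlier indicator,
  matching the pairing of hazard ratios with log-rank p-values in
  reported per-gene tables.

## Known limitations

The central quantitative one: per-gene quantile calling can flag at most
`(1 − q_high)` of samples per gene. When an amplicon's prevalence exceeds
that fraction (0.25 vs 0.10 at the defaults), only the most strongly
amplified carriers can ever be called — a counting bound caps per-sample
call sensitivity at `2(1 − q_high)/prevalence` under the ≥ 50%-marker
rule, and the realistic value with shared carrier dosage is about
`(1 − q_high)/prevalence` ≈ 40%. Region *discovery* and carrier-vs-none
hazard ratios are much less affected (the called carriers are true
carriers; specificity stays near 1), but per-sample sensitivity at high
prevalence is intrinsically poor, and the estimated HR is attenuated
toward the uncalled-carrier mixture. For cohorts where most samples carry
the event, quantile calling is the wrong instrument; a mixture model or
explicit copy-number data would be needed.

Other limits: the FISH thresholds are in-sample optimisations and must be
validated externally; the recurrence score is relative, not the
commercial 0–100 scale; survival modelling assumes proportional hazards
and independent censoring; no multiple-testing correction is applied at
the per-gene screen stage (by design — the positional FDR stage is the
error-control gate, mirroring the screen-then-confirm architecture).
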