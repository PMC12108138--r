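---
title: "Stability-selected polygenic risk scores: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability-selected polygenic risk scores: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabprs)
```

## The problem

A polygenic risk score (PRS) summarises an individual's genetic liability
for a quantitative trait as a weighted sum of allele dosages,
$\mathrm{PRS}_i = \sum_j \beta_j G_{ij}$, with weights taken from a
genome-wide association scan (GWAS). In small cohorts the content of a
clumping-and-thresholding (C+T) score is notoriously unstable: removing or
adding a handful of samples reshuffles the marginal p-values and with them
the selected variants. `stabprs` implements an iterative resampling
pipeline that addresses this instability by *stability selection*: the
cohort is repeatedly split, a best C+T score is derived on each split, and
the final score is assembled from the variants that are selected
repeatedly, with effect sizes re-estimated once on the whole cohort.

The package is organised in the classic R modelling idiom: one fitting
function, `prs_stability()`, returns a classed object with `print()`,
`summary()`, `coef()`, `predict()`, `fitted()`, `residuals()` and `plot()`
methods; every pipeline stage underneath it (QC, pruning, PCA, scan,
clumping, scoring, aggregation, validation) is also exported on its own.

## The procedure

For each of `n_iterations` (default 100) iterations:

1. **Partition.** The cohort is split without replacement into a source
   set (`split`, default 80%) and a target set (20%). The split is fresh
   and random in every iteration; "bootstrap" refers to this iteration
   scheme, not to with-replacement resampling.
2. **Source-set QC.** Variant filters (imputation INFO, call rate, minor
   allele frequency), then sample filters (call rate), then LD pruning
   and PCA with Tracy–Widom selection of significant components are all
   recomputed on the source set.
3. **Association scan.** For each variant, ordinary least squares of the
   trait on the effect-allele dosage with sex, age and the selected PCs
   as covariates. Samples with a missing dosage are dropped per variant
   (not imputed), so standard errors remain honest; p-values use the t
   distribution with the residual degrees of freedom.
4. **C+T derivation on the target.** Summary statistics are clumped
   against the target genotypes (greedy, most significant variant first),
   then a score is built at each p-value threshold on a fixed grid and
   the trait is regressed on score plus covariates in the target. The
   threshold maximising the *incremental* $R^2$ — the $R^2$ of the model
   with the score minus the $R^2$ without it — wins. An empirical
   p-value (fraction of phenotype permutations whose best-threshold
   incremental $R^2$ reaches the observed one) guards the threshold scan
   against overfitting.

The per-iteration best incremental $R^2$ values form the **baseline
distribution**. Variants are then aggregated by their **appearance
frequency** across the per-iteration best models; for every distinct
frequency cut-off at or above `min_freq` a candidate SNP set is formed
(sets are nested by construction). Candidates are narrowed to the local
maxima of the mean-incremental-$R^2$ profile, assigned an empirical
bootstrap p-value (the fraction of baseline values exceeding the
candidate's mean $R^2$), and the best narrowed candidate is finalized by
re-estimating all its weights from a whole-cohort scan with the same
covariates. Hold-out validation (`holdout_validate()`) and association
with a secondary phenotype (`secondary_association()`) complete the
analysis.

## Scoring conventions

Raw scores follow the average-per-observed-allele convention:
$s_i = \sum_j \beta_j G_{ij} \,/\, (2 m_i)$ with $m_i$ the number of model
variants observed for sample $i$; a missing dosage contributes the
variant's expected dosage $2\hat p$. A plain weighted sum is available via
`average = FALSE`. Variants whose allele labels are swapped relative to
the model are flipped (dosage $2-G$); unmatchable variants are dropped
with a message, and more than 50% unmatched is an error. For reporting,
scores are min-max scaled to $[0, 1]$ (0.5 when degenerate). Reported
scores never print an empirical p of literal zero; `format_empirical_p()`
renders it as `< 1/n`.

## Tunable parameters

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| `min_info` | 0.9 | score | exclude poorly imputed variants; *strictly below* removes |
| `min_variant_callrate` | 0.95 | fraction | conventional variant completeness |
| `min_maf` | 0.05 | frequency | common variants only; folds to $\le 0.5$ |
| `min_sample_callrate` | 0.90 | fraction | conventional sample completeness |
| `window_kb` (prune) | 250 | kb | conventional pre-PCA pruning window |
| `r2_threshold` (prune) | 0.2 | $r^2$ | conventional pre-PCA setting |
| `clump_window_kb` | 250 | kb | the C+T tool convention |
| `clump_r2` | 0.1 | $r^2$ | the C+T tool convention |
| `p_grid` | 5e-8 … 1.0 | p | standard C+T threshold ladder |
| `n_permutations` | 10000 | count | resolution of the empirical p |
| `n_iterations` | 100 | count | resampling depth |
| `split` | 0.8 | fraction | source share of each partition |
| `min_freq` | 10% of iterations | count | the 10-of-100 stability floor, scaled to the iteration count |
| `alpha` | 0.05 | level | Tracy–Widom significance |
| `max_pc` | 20 | count | cap on selected components |

All boundary semantics are "remove if strictly below the threshold",
matching the exclusive phrasing of the INFO rule; applying one rule set
consistently keeps the filters idempotent.

## Tracy–Widom component selection

PCA uses mean-imputed dosages centred at $2\hat p$ and divided by
$\sqrt{2\hat p(1-\hat p)}$. The number of significant components is
chosen sequentially: for the leading eigenvalue of the remaining
spectrum, an effective marker count is estimated from the spectrum's
first two moments, $\hat n = (m+1)S_1^2/(mS_2 - S_1^2)$, the eigenvalue
is standardized with the corresponding centring and scale, and compared
with the upper-$\alpha$ quantile of the Tracy–Widom ($\beta = 1$) law;
testing stops at the first non-significant eigenvalue. The TW quantiles
come from a bundled table computed from the Painlevé II representation
of the distribution (see `R/tw-table.R` for provenance and spot checks).

Two properties worth knowing:

* On cohorts of *unlinked* variants the selection is calibrated: the
  probability of selecting at least one component on unstructured data is
  close to $\alpha$ (checked by simulation in the test suite), and
  two-population cohorts with $F_{st} = 0.05$ always yield at least one.
* Residual LD inflates the leading eigenvalues relative to the white
  null. After pruning at $r^2 \le 0.2$, strongly linked panels can still
  push the statistic far above the threshold, so on LD-dense synthetic
  cohorts the selection often runs to `max_pc`. This is a known property
  of eigenvalue tests under LD, not an artifact of this implementation;
  the spurious components act as harmless extra covariates in the scans.
  Aggressive pruning (e.g. $r^2 \le 0.05$) restores calibration.

## The synthetic-cohort generator

`simulate_cohort()` emulates what the pipeline needs from imputed-array
cohort data with no access to any real cohort:

* **LD blocks** via an exchangeable latent-Gaussian copula per block,
  thresholded at the allele frequency, two haplotypes summed to a 0/1/2
  dosage. `within_block_rho` controls LD; blocks are independent and
  separated by 1 Mb so pruning/clumping windows never straddle them.
* **Population structure** via Balding–Nichols subpopulation frequencies
  around a uniform ancestral frequency.
* **An additive trait** with `n_causal` Gaussian effects on standardized
  dosages, a +12.7 trait-unit male offset and a small age slope
  (configurable), scaled so the genetic variance is exactly
  `heritability` × `trait_sd`² in-sample — heritability is a fraction of
  *total* trait variance, covariates included. The default
  `trait_sd = 9.5` leaves room for the sex-offset variance.
* **A secondary phenotype** (diastolic blood pressure) sharing a
  fraction `secondary_rho` of its residual SD with the standardized
  genetic value, plus BMI/weight derived from height, systolic pressure
  with no genetic share, and a sex-dependent antihypertensive-medication
  flag (12.2% / 38.2%).
* **Degradation**: per-entry missingness, uniform per-variant INFO
  scores, and an engineered subset of samples below the 0.90 call-rate
  bar.

What it does *not* emulate: realistic recombination maps and LD decay
within blocks, imputation dosage uncertainty beyond a scalar INFO,
non-additive effects, relatedness, or X-chromosome dosage models.
Passing tests on these cohorts demonstrate the pipeline's statistical
behaviour (calibration, recovery, determinism), not performance on any
real population.

## Design choices where the design was open

* **Candidate rescoring.** A frequency-thresholded candidate needs a
  per-iteration $R^2$ distribution. We score the candidate set on each
  iteration's target with the effects *as returned in that iteration's
  best model* (variants outside that iteration's model contribute
  nothing). The alternative — weighting every candidate variant with the
  iteration's full-scan betas — makes iteration $i$'s value depend on
  variants chosen by other iterations whose sources contain iteration
  $i$'s target samples; on zero-heritability cohorts that information
  leak inflates candidate $R^2$ an order of magnitude above baseline and
  drives every bootstrap p to zero. The restricted form keeps each
  iteration's value a function of its own partition, so the null behaves
  like the baseline while genuine signal still yields the
  characteristic frequency-profile of mean $R^2$.
* **Per-iteration PCs for the target regression.** Source-set PCs cannot
  be transferred to target samples without projection (out of scope), so
  target-set regressions use the whole-cohort PC loadings restricted to
  the target rows; source-set scans use freshly recomputed source PCs
  (`recompute_pca = TRUE`, with a switch).
* **Pruning is per chromosome** and scans variant-by-variant, which
  guarantees the no-pair-above-threshold invariant exhaustively; the
  `step` argument is accepted for configuration compatibility but does
  not change the result.
* **The N in the score formula.** Published renditions of the C+T score
  sometimes include a population size N; it has no place in a
  per-individual score and is interpreted here as normalization
  bookkeeping — the implemented normalization is per observed allele.
* **Local maxima** of the candidate profile are strict and compare
  immediate neighbours only (endpoints to their single neighbour), for
  determinism.
* **Ties in clumping p-values** break by genomic position, then variant
  id, for determinism.
* **Pooled-variance t-tests** by default in descriptive tables (Welch
  via `var_equal = FALSE`).
* **`min_freq` scales with the iteration count** (10% rounded up), so
  the conventional 10-of-100 floor remains meaningful in
  demonstration-scale runs with few iterations.
* **Final candidate choice.** The first local maximum on the
  frequency-ordered profile (the lowest cut-off, i.e. the largest stable
  set) is finalized. Under genuine signal the profile peaks at the
  frequency floor, so this coincides with the global maximum — and with
  the published behaviour of the motivating analyses, whose final scores
  were the largest aggregated sets. Under weak or no signal it avoids
  promoting a small high-cut-off candidate whose mean $R^2$ is inflated
  by chance cohort-level correlations (see the leakage discussion
  above). All narrowed candidates and their bootstrap p-values remain in
  the fitted object for manual inspection.

## Numerical choices

Per-variant OLS runs in compiled code with exact per-variant dropping of
missing-dosage samples, implemented by downdating the cohort-level
cross-products; results match a normal-equations oracle to 1e-10.
Incremental $R^2$ values are computed through the Frisch–Waugh–Lovell
decomposition (residualize score and trait against the covariates once),
which also vectorises the permutation scan. Permutation p-values are
reported as plain fractions; zero is rendered as `< 1/B`. Degenerate
cases: monomorphic variants are excluded from scans, zero-variance
columns standardize to zeros, min-max scaling of a constant score yields
0.5, and rank-deficient covariate matrices raise an error naming the
collinear columns.

## Problem sizes used by the test suite

The packaged tests exercise the pipeline at desk scale, chosen as the
smallest sizes at which the statistical claims are meaningful: oracle
equivalence on panels of tens of variants; null calibration on 20
cohorts of 500 samples × 2,000 variants with 10 iterations; parameter
recovery on 10 cohorts of 2,000 samples × 5,000 variants (200 causal,
$h^2 = 0.5$) with 25 iterations; Tracy–Widom calibration over 200
unstructured cohorts; and a deterministic end-to-end run at 600 × 2,000.
Permutation counts are reduced in these runs (50–200) since only the
resolution of the empirical p, not the selection path, depends on them.

## Known limitations

* The bootstrap p-value compares a candidate's *mean* $R^2$ with the
  spread of per-iteration maxima; it is a stability diagnostic, not a
  formal test, and its granularity is $1/n_\mathrm{iterations}$. It is
  also anti-conservative on null cohorts: mid-frequency candidate sets
  consist of the variants that by chance correlate with the trait over
  the whole cohort — which is why they keep being selected across
  overlapping sources — and every evaluation target is a subset of that
  same cohort, so such candidates can reach bootstrap p = 0 without any
  real signal (the test suite measures this on zero-heritability
  cohorts). Only evaluation on samples never touched by the ensemble
  (the hold-out validation stage) is free of this internal leakage; a
  small bootstrap p should therefore never be read as external evidence
  on its own.
* Tracy–Widom selection over-selects under residual LD (above).
* With few iterations the frequency floor is coarse; candidates at
  adjacent cut-offs can coincide.
* The generator's exchangeable within-block LD makes clumping easier
  than real decay patterns; causal-enrichment figures on synthetic data
  are optimistic in that specific sense.
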