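---
title: "Signature-reversal drug screening: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature-reversal drug screening: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revscreen)
```

## The screening model

`revscreen` ranks a library of drug perturbation signatures by their ability
to *reverse* a disease expression signature. The underlying assumption is the
connectivity-mapping one: if a disease state is characterized by a
reproducible set of up- and down-regulated genes, then a compound that drives
those genes in the opposite direction in an independent cellular system is a
candidate for restoring the normal state. The pipeline makes that operational
in four stages: preprocessing, differential expression, three-way
drug–disease scoring, and a rank ensemble.

Nothing in the pipeline is stochastic: given the same matrices and
parameters, every stage — including the final report files — is reproducible
byte for byte. Randomness only enters through the synthetic-data generators,
which take an explicit `seed` argument and never touch the session's global
RNG state.

## Preprocessing

Three steps, in a fixed order, for continuous (microarray-like) matrices:

1. **Outlier winsorization**, per sample, clamping values outside the
   (`winsor_low`, `winsor_high`) empirical quantiles. The default (0.01,
   0.99) trims tail artifacts while preserving the bulk scale. We clamp
   values rather than drop samples: it is deterministic, keeps the design
   intact, and is the mildest intervention consistent with "outlier
   handling". All quantiles throughout the package are linear-interpolation
   (type 7) quantiles, so a single convention covers every code path.
2. **Quantile normalization** maps every sample onto the mean
   order-statistic distribution. Ties within a sample receive the mean of
   the reference values their rank range spans, so tied inputs stay tied.
   The operation is idempotent on tie-free data (and the test suite asserts
   equality of sorted columns to 1e-12).
3. **Gene standardization** to mean 0 / sample SD 1 per row; constant rows
   map to zeros rather than NaN. Standardization puts the DEG effect-size
   threshold on a comparable scale across genes and platforms.

Count matrices are deliberately excluded from all of the above; the only
count-space operation is the quality filter that keeps genes with at least 5
counts in at least 8 samples (both bounds inclusive). Mixing count and
intensity normalization regimes is a classic source of silent errors, so the
two data kinds never share a code path.

## DEG selection

Per gene we run one parametric and one nonparametric two-sample test — Welch
t with Satterthwaite degrees of freedom, and Mann–Whitney with an exact null
for combined n ≤ 20 without ties and a tie- and continuity-corrected normal
approximation otherwise — and combine them conservatively as the maximum of
the two p-values. A gene must therefore convince both tests, which suppresses
calls driven by a single outlier (t) or by borderline rank patterns (U). The
combined p-values are BH-adjusted; a call additionally requires
|case − control mean difference| ≥ `lfc_min` (default 1.0, in standardized
units since the screening arm standardizes genes; set it to match your scale
if you skip standardization).

The per-gene tests are implemented row-vectorized so that a 2000-gene screen
costs milliseconds; the test suite cross-checks them against `stats::t.test`
and `stats::wilcox.test` on randomized inputs.

With small groups the conservative combination is deliberately blunt: the
rank-sum test's smallest achievable two-sided p with 5 + 5 samples is ≈
0.008, which cannot survive BH correction across thousands of genes, so
cohorts below roughly 8 + 8 samples will yield empty DEG sets under the
default `tests = "both"`. That is a property of the statistics, not a bug;
use `tests = "welch"` for very small pilot cohorts.

For drug libraries distributed as per-drug DEG tables,
`remove_common_genes()` resets genes called in more than `max_frac` (default
0.33) of all drugs to non-significant in every table. This deterministic
frequency filter removes assay- or tissue-common responses (stress programs,
vehicle effects) that would otherwise dominate every comparison.

## The three scores

**Enrichment test (ET).** The classic unweighted two-sided KS running-sum
statistic, chosen over score-weighted variants because it depends only on the
rank positions of the set — which makes it robust to the incomparable score
scales of disease and drug profiles and admits an exact brute-force oracle
(the test suite enumerates every set of size ≤ 3 in every list of length ≤ 8
and checks equality to 1e-12). The orientation
`et = (es_down − es_up) / 2` makes positive values mean therapeutic reversal.
Reversing a ranking exchanges the two one-sided deviations up to a 1/n shift,
so mimickers and reversers score symmetrically on symmetric configurations.

**Similarity test (ST).** Cosine similarity between the two signed DEG score
vectors. The vector space is the union of the two profiles' DEG sets
intersected with both measured universes, zero-filled where a gene is
measured but not differential. A full-transcriptome cosine was rejected: the
thousands of non-differential genes would dilute the angle toward 90° for
every drug, and the DEG-restricted vector is what "vectorized DEG expression
levels" means operationally. θ is reported in degrees, and the ranking uses
−cos so that larger angles (stronger opposition) rank higher.

**Contingency test (CT).** Two one-sided Fisher exact tests — drug-up genes
among disease-down genes and vice versa — on the universe of genes measured
in both profiles. The paper-style "and vice versa" pair needs a combination
rule; we use Fisher's method (χ², 4 df) because the two directional overlaps
are computed on (nearly) disjoint gene sets and behave as independent
evidence. `ct = −log10` of the combined p, so larger is better and the value
is unbounded above.

Signatures cap each direction set at `cap = 150` genes (ties broken by gene
id for determinism). For drug profiles given as raw score vectors, the up/down
sets are the top positive and bottom negative scorers under the same cap —
score-vector profiles carry no significance calls, so magnitude rank is the
only available criterion. Multi-cell-line profiles are aggregated before
scoring by the per-gene median across lines (mean available), treating lines
as replicates of one consensus perturbation.

A drug whose sets vanish in the shared universe, or whose ST vector is zero,
is scored as missing with a warning and placed after all fully-scored drugs
in the ensemble rather than being silently dropped.

## Ensemble and intersection

Each test ranks drugs in its reversal direction with average ranks for ties;
the normalized rank `(n + 1 − rank) / n` lies in (0, 1] and the final score is
the equal-weighted mean of the three (weights are exposed — there is no
principled basis for unequal defaults, and equal weights keep the final score
interpretable as a mean rank percentile). Final ordering is descending with
ties broken by drug id, so duplicated inputs produce adjacent ranks.

Cross-cohort candidates are the intersection of the per-cohort top-k sets
(default `top_k = 10`, a flag). A score threshold was the alternative; top-k
was chosen because ensemble scores are rank-based and not comparable across
cohorts with different DEG counts. An optional exclusion list (e.g. prior
anticancer agents or failed-trial compounds) is applied to the library before
ranking.

## What the synthetic generator emulates

`simulate_cohort()` produces microarray-like matrices: per-gene Gaussian
baselines (mean 7, SD 1 on a log-intensity-like scale) plus independent
Gaussian noise, with planted genes shifted by `effect × noise_sd` in case
samples. The reference conditions used throughout the validation suite are
2000 genes, 10 + 10 samples, 50 + 50 planted genes at `effect = 3` — a
clearly-powered two-group design of the size typical for public disease
cohorts. `simulate_drug_library()` plants reversers (−strength × disease
pattern), mimickers (+strength), and pure-noise nulls, each drug observed in
3 cell lines sharing its true pattern with independent per-line noise, with
`reversal_strength = 2` as the reference. `simulate_counts()` draws negative
binomial counts (dispersion 0.1) and forces a chosen fraction of genes below
the 5-counts-in-8-samples rule, recording exactly which — pass/fail truth is
guaranteed by construction, not merely highly probable.

Features of real data the generator deliberately omits: probe-level effects,
batch structure beyond scale shifts, correlated gene modules,
platform-specific intensity distributions, and partially overlapping gene
universes between disease and drug profiles. Passing tests therefore
demonstrate that the machinery is correct and calibrated under its stated
noise model — not that any particular real cohort will yield the same
recall; effect sizes and noise in public datasets are unknowable in advance
and were not estimated here.

## Validation properties and problem sizes

The acceptance test suite asserts, among others: exhaustive ET-oracle
equality; hypergeometric-tail equality on 500 random configurations
(including the exact rational 155/4845 for the 20-gene worked example);
quantile-normalization contracts on 100 random matrices; null-cohort DEG
calls ≤ 1% of genes over 20 seeds and planted recall ≥ 0.9 at effect 3;
planted-reverser rank 1 in ≥ 95% of 40 replicate screens plus a χ²
uniformity check of a null drug's rank over 200 replicate libraries; shared
planted reversers appearing in the two-cohort top-10 intersection in ≥ 95%
of 20 replicates; and exact count-filter/truth agreement. These replicate
counts keep the full suite around two minutes on a single core while leaving
the binomial noise of each rate estimate well inside the asserted margins.

## Known limitations

- The ensemble is rank-based; absolute final scores are not comparable
  across libraries of different sizes.
- Missing-score drugs are ranked last rather than given partial-evidence
  scores.
- The frequency-based common-gene filter is a deterministic stand-in for
  learned common-response removal; with very small libraries (2–3 drugs) its
  frequency estimates are coarse.
- No paired designs, covariates, or moderated variance estimators in the DE
  stage; cohorts with confounded structure need external adjustment first.
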