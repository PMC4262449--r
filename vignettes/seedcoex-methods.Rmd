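---
title: "Methods: seed-gene spatial and differential co-expression"
author: "seedcoex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed-gene spatial and differential co-expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedcoex)
```

## The problem

A single *seed gene* (in the motivating application, the Parkinson's gene
SNCA) is profiled against a *gene set* (the 73 genes of the
interferon-gamma-mediated signaling pathway, GO:0060333) in three
complementary designs:

1. **Spatial co-expression.** Within one donor brain, expression is
   measured across many regions. The Spearman correlation across regions
   between the seed and each other gene is that donor's co-expression
   profile; the mean over the gene set summarises how coherently the set
   tracks the seed.
2. **Developmental trajectory.** With one such value per donor and donors
   spanning prenatal weeks to adulthood, the Spearman correlation of the
   per-donor value against age asks whether the seed-to-set coupling
   strengthens or weakens over the lifespan.
3. **Disease rewiring.** In case/control cohorts the sample unit is a
   subject, not a region. Within each condition group the seed-to-gene
   Spearman correlation is computed across subjects; the contrast of the
   two correlation patterns (not of expression levels) is differential
   co-expression.

## Preprocessing: within-sample ranking

Every dataset is first rank-normalised per sample: each column of the
gene-by-sample matrix is replaced by average ranks (1 = lowest expression).
This removes cross-sample scale and batch differences while preserving each
sample's gene ordering; every downstream statistic is computed on these
ranks, and Spearman correlation re-ranks each gene's profile across samples
on top. The double ranking makes all results invariant to any monotone
per-sample transform of the raw data.

One numerical consequence worth knowing: with a small gene universe the
within-sample rank of a gene is a noisy (though asymptotically exact)
monotone transform of its value, which attenuates cross-region correlations
toward zero. We measured the attenuation on the simulator: at a universe of
500 genes a planted population Spearman of −0.30 is measured around −0.27;
at 2,000 genes the bias is below 0.01. Convergence tests against the
closed-form population value are therefore run at a 2,000-gene universe,
while small-universe tests compare against a large-sample oracle run
through the identical pipeline.

## Statistics

* **Spearman correlation** with average-rank ties throughout
  (`spearman_rho`). Correlations within numerical epsilon of ±1 are snapped
  to exactly ±1, so two-region donors report exactly −1 or +1.
* **Empirical p-values** use the add-one rule $p = (b+1)/(n+1)$, where $b$
  counts resamples at least as extreme as the observation in the stated
  tail; $p$ can never be 0, and beating 10,000 resamples gives
  $p = 1/10001 < 10^{-4}$. Two-sided p-values are $2\min(p_{lower},
  p_{upper})$ capped at 1. Tails are always explicit arguments, never
  inferred from the data.
* **Paired Wilcoxon signed-rank** and **Wilcoxon rank-sum** wrap the
  standard implementations (exact where tie-free and small, normal
  approximation otherwise); both are verified in the test suite against
  exhaustive enumeration oracles for $n \le 8$.
* **Fisher combination**: $-2\sum\ln p_i$ on $2k$ degrees of freedom. The
  direction-aware "trend" variant folds each two-sided $p_i$ to one-sided —
  $p_i/2$ if the study's effect sign matches the consensus sign (the sign
  of the sum of study signs), $1 - p_i/2$ otherwise — before combining.
  The external meta-analysis tool used for the published meta p-values does
  not document its exact trend weighting, so both plain and trend variants
  are reported and neither is claimed to reproduce the published meta
  values digit for digit.
* **Inversion fraction**: the proportion of evaluated set genes with
  strictly negative control correlation *and* strictly positive case
  correlation. A zero on either side never counts. The denominator is
  always the number of set genes actually evaluated in that cohort and is
  reported alongside, because probe filtering makes it vary by dataset.
* **Label permutations** preserve group sizes: condition labels are
  shuffled, both group correlation patterns recomputed, and the mean
  correlation change and inversion fraction collected per shuffle
  (default 1,000 shuffles, seeded). The mean-change test is two-sided by
  default; the inversion test is upper-tailed because an excess of
  inversions is the only interesting direction.
* **Specificity scans** replace either the gene set (random same-size draws
  from the measured universe, seed excluded, real set not excluded — the
  expected overlap is negligible) or the seed itself (every universe gene
  in turn). The seed-replacement count $k$ is reported with both
  conventions, $k/N$ and $(k+1)/(N+1)$; the add-one form is the decision
  value because it cannot be zero. Ties with the seed statistic are
  reported but not counted as beating it.

## Leave-one-region-out attribution

For each region $r$, $\delta(r) = \bar\rho(\text{all regions}) -
\bar\rho(\text{all except } r)$. With a negative full correlation, the most
negative $\delta$ marks the region whose removal moves the mean correlation
most toward zero — the top-contributing region. The sign convention is
recorded in the output because the opposite convention is equally common.
Each $\delta$ is asserted in the tests to equal direct recomputation on the
reduced panel, exactly.

## The synthetic-data generator

A deliberately minimal single-latent-factor Gaussian model generates all
test data with known ground truth:

* **Spatial donor**: each region $r$ carries $z_r \sim N(0,1)$; the seed is
  $z + \varepsilon$, each set gene $c(\text{age})\,z + \varepsilon$, each
  background gene pure $\varepsilon$, with $\varepsilon \sim N(0,
  \sigma^2)$ independent everywhere. Values are exponentiated so matrices
  arrive on a positive, skewed scale and the ranking path is exercised.
  The planted Pearson correlation between seed and a set gene is
  $c/\sqrt{(1+\sigma^2)(c^2+\sigma^2)}$ and the population Spearman follows
  the bivariate-normal identity $\frac{6}{\pi}\arcsin(\rho/2)$ — the
  closed-form oracle used in the tests.
* **Loading over age**: $c(\text{age}) = c_0 + c_1\,\text{age}$ with
  defaults $c_0 = 0.15$, $c_1 = -0.016$, $\sigma = 1$: the set's population
  Spearman correlation with the seed then runs from about $+0.10$ before
  birth to about $-0.30$ at age 40, matching the magnitude of the published
  prenatal-to-adult drop. Ages are signed years with birth at zero (a donor
  at 8 post-conception weeks is $(8-40)\cdot 7/365.25 = -0.61$); the
  default study uses 41 donors from −0.61 to 40 years with 14 regions each,
  mirroring the donor structure of public developmental brain resources
  (2–16 sampled regions, most donors ≥ 14).
* **Cohort**: each subject carries a scalar $z_s$; a fraction $f$ of set
  genes (the *rewired* genes) use `loading_control` in controls and
  `loading_case` in cases, the rest use `loading_control` in both groups.
  Default loadings are −0.4/+0.4 with $\sigma = 0.8$, giving a planted
  within-group Spearman magnitude of about 0.33 — comparable to the
  published control-group means (0.04–0.23) while strong enough that
  per-gene correlation signs are recoverable at realistic cohort sizes
  (which is precisely what the parameter-recovery checks assert). The
  fixture corpus uses the published cohort sizes 25, 39, 29, 33 plus a
  105-subject contrast cohort with no rewiring.

What the generator does **not** emulate: structured region–region
covariance (real neighbouring regions correlate), platform-specific noise
(microarray vs RNA-seq), probe-level effects, missingness patterns, and
multi-factor co-expression structure. Passing tests therefore demonstrate
that the statistics recover what was planted under a clean latent-factor
model — not that the biological conclusions of any particular study are
correct.

## Design choices where the design was open

* **Age axis**: one signed real number spanning prenatal and postnatal
  donors, rather than separate stage variables; the prenatal/postnatal
  split is at 0.
* **Averaging order**: probes are averaged to genes, and samples to
  regions, on the expression scale *before* ranking; ranking is a global
  preprocessing step applied once.
* **Seed exclusion**: the seed is excluded from its own gene set and from
  gene-universe summaries, avoiding a guaranteed $\rho = 1$ inflating
  means.
* **Two-region donors** are included by default (flagged, since their
  correlations are forced to ±1) with a switch to exclude them.
* **Brain-wide age analysis** is provided in both a per-donor mode
  (one value per donor, rank-sum between donor groups) and a pooled-sample
  mode (samples pooled across donors per group, paired Wilcoxon over
  per-set-gene correlations), because published analyses state the
  summarisation level only for some figures.
* **Contrast cohorts** (e.g. blood rather than the target tissue) are
  excluded from meta-combination by a configuration flag, not by hard-coded
  tissue logic.
* **p = 0 inputs** to combination are clamped to the smallest positive
  double: add-one permutation p-values can never be zero, but user-supplied
  analytic ones might underflow.

## Problem sizes used in the tests

The shipped test suite and acceptance script regenerate all data at run
time. Calibration uses 500 simulated null cohorts (15+15 subjects, 73 set
genes, 199 label shuffles each) and 500 simulated null developmental
studies (10 donors, 199 random sets each); parameter recovery uses 40+40
subjects per cohort and 100 simulated 41-donor studies; exhaustive-oracle
comparisons use universes of up to 60 genes. These sizes keep the whole
suite in the tens of minutes on one CPU while leaving the binomial
confidence bands for the calibration checks tight enough to be meaningful.

## Known limitations

* Spearman trend p-values over donors are analytic (t approximation), not
  exact, and treat donors as exchangeable; family structure or repeated
  donors would violate this.
* The genome-wide scans recompute correlations for every gene and scale
  linearly in universe size; on a full transcriptome they are minutes, not
  seconds.
* The inversion fraction is a discrete statistic; its permutation p-value
  is slightly conservative when many shuffles tie with the observed value.
* No multiple-testing correction is applied inside the package beyond what
  the scans' empirical conventions imply; per-gene tables expose raw
  p-values for the caller to adjust.
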