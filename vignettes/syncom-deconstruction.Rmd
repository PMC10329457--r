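---
title: "Deconstructing synthetic communities: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconstructing synthetic communities: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syncomr)
```

`syncomr` packages the statistics of a synthetic-community (SynCom)
deconstruction campaign: which strains co-occur, which genomic loci are
restricted to a focal clade, which strains inhibit root growth and which
partners revert that inhibition, whether a marker gene set moves between
treatments, and which taxa are core across surveys. This vignette explains
the underlying models, the tunable parameters and their defaults, what the
simulators do and do not emulate, and the numerical conventions that matter
for reproducing results.

## Co-occurrence modules

The input is a strains × samples relative-abundance matrix. Three steps:

1. **Standardization.** Each strain's abundances are divided by that
   strain's mean across all samples, so every retained row has mean 1. This
   removes per-strain load differences while preserving the sample-to-sample
   profile. All-zero strains cannot be standardized and are dropped with a
   warning (returned in the `dropped` attribute); they carry no
   co-occurrence information.
2. **Dissimilarity.** `d(i,j) = 1 − r(i,j)`, Pearson correlation across
   samples, range [0, 2]. Perfectly anti-correlated strains are maximally
   distant. The alternative `(1 − r)/2` (range [0, 1]) is available via
   `transform = "half_one_minus_r"` but is not the default; it is a
   monotone rescaling and changes no tree topology, only heights.
3. **Clustering.** `hclust(method = "ward.D2")` on that dissimilarity:
   Ward's minimum-variance criterion with the Lance–Williams update applied
   to *squared* dissimilarities and heights reported on the dissimilarity
   scale. The test-suite contains an independent brute-force agglomerator
   that recomputes every pairwise merge cost at every step and confirms,
   height by height and partition by partition, that this is what `hclust`
   computes. The tree is cut into `k` modules; `k = 4` by default because a
   four-module structure is the canonical deconstruction target, but no
   automatic model selection is attempted — `k` is an explicit analysis
   choice.

Strains are sorted lexicographically before clustering, which makes the
output invariant to input row order; remaining ties inside `hclust` are then
resolved identically for identical inputs.

**Family enrichment.** For each module and family present in it, the
upper-tail hypergeometric probability of drawing at least the observed
number of family members in a module-sized draw from the assigned strains.
The universe is *all strains assigned to modules* (i.e. all strains
surviving the zero-row drop) — the natural choice when the whole community
is clustered, though other universes (e.g. plant-detected strains only) are
defensible; the universe is whatever table you pass in. P values are
BH-adjusted over all (module, family) pairs and flagged at `q < 0.1`.

## Clade-specific hotspots

Given gene → orthogroup membership over a genome universe split into a
focal clade and a background set:

* **Selection.** An orthogroup is clade-specific when present in **every**
  focal genome (clade core) and in strictly fewer than
  `max_bg_prev × n_background` background genomes (default 5 %). Prevalence
  counts genomes carrying ≥ 1 member gene, never gene copies. With 175
  background genomes, presence in 8 (4.57 %) passes and presence in 9
  (5.14 %) fails — the boundary is tested at exactly this arithmetic.
* **Assembly.** On one declared reference genome, selected genes are sorted
  by start per scaffold and merged greedily while the *intervening
  distance* — `next start − running max end − 1` — is strictly below
  `gap_bp` (default 10,000). Intervening distance was chosen over
  start-to-start spacing as the natural reading of "less than 10 kb from
  each other"; both are strict and the threshold is configurable.
  Overlapping genes have negative gaps and always merge. A run is reported
  when it holds at least `min_genes` (default 10) distinct orthogroups;
  paralogs therefore do not inflate the filter, though the member-gene
  count is reported alongside. The inclusive `>= 10` default reflects the
  "at least 10" phrasing that matches the canonical 12-hotspot outcome; an
  exclusive variant (`strict = TRUE`) and a gene-count filter
  (`count_by = "genes"`) cover the stricter alternative reading.
* **Coordinates** are 1-based inclusive throughout (GFF3 convention);
  `interval_length_kb` is `round((end − start + 1)/1000)` with R's
  round-half-to-even, and BED export converts to 0-based half-open.

## RGI phenotyping

A strain is an **RGI inducer** when its mean primary-root elongation in
mono-association, pooled over all seedlings, plates and experiments, is
strictly below 3 cm; a mean of exactly 3.0 cm is non-RGI. Pooling (rather
than per-experiment means) was chosen because the plate is not a blocking
factor in the decision rule; a stratified analysis can be had by filtering
the table beforehand.

**Reversion** of an inducer by a partner is tested per partner with a Welch
two-sample *t*-test of combined-inoculation elongation against
inducer-alone elongation, one-sided (combined > alone) because reversion is
a directional claim (`alternative = "two.sided"` is available). P values
are BH-adjusted across the partners of that inducer and reversion is called
at `q < 0.05` with a non-negative mean difference. This replaces
ANOVA + Tukey letter displays: the letters are a presentation device,
whereas a per-partner test plus FDR is a reusable decision rule, and it
matches the *t*-test + FDR analysis used in community drop-out comparisons.

**Standardization to control** divides each measurement by the mean of the
no-bacteria control within its genotype, making genotypes comparable on a
dimensionless scale where the control mean is exactly 1 (and the operation
idempotent). **IQR bands** use the linear-interpolation percentile
convention (R `quantile` type 7): for `c(1, 2, 3, 4)` the band is
(1.75, 3.25). The convention is documented because these bands are drawn in
figures.

## Gene-set resampling test

The matrix is normalized expression (any variance-stabilizing pipeline;
that step is upstream of this package) optionally z-scored per gene.
Z-scoring uses the sample SD (n − 1, base R `scale` convention); the choice
affects only a constant factor and never the permutation p value. The
observed statistic is the difference between treatments of the mean
expression over the set's genes, equal-weighted over genes. The null is the
same statistic for `B` random gene sets of equal size drawn without
replacement from **all** genes — the target set is not excluded, matching a
resampling null drawn "from the expression matrix"; with thousands of genes
the inclusion is immaterial. `p = (1 + #extreme)/(B + 1)`, two-sided by
default since the direction of a marker shift is not assumed
(`greater`/`less` flags available); the +1 correction keeps p valid and
bounded below by 1/(B+1). Determinism: the only randomness is the set draw,
governed by `seed`.

Under the null (no planted shift) the test is calibrated by construction;
the acceptance suite verifies a type-I error in [0.03, 0.07] at α = 0.05
over 1,000 simulated datasets with B scaled down to 500 to keep the suite
inside its runtime budget — calibration is a property of the p-value
construction, not of B, so the scale-down does not weaken the check. Power
is checked at the full B = 10,000 with a 2-SD planted shift of 12 markers
among 2,000 genes, where p reaches the permutation floor.

## Prevalence rules

All thresholds are strict inequalities, and all are parameters:

| rule | default | boundary behaviour |
|---|---|---|
| sample kept | reads > 1,000 | exactly 1,000 reads → removed |
| present in sample | RA > 0.01 % | exactly 0.01 % → absent |
| widespread | present in > 80 % of sites | 4/5 sites → not widespread |
| present in species | > 70 % of its samples | exactly 70 % → not present |
| core | present in all species | any failing species disqualifies |

Site-level presence for the widespread rule is "present in ≥ 1 sample of
the site". The phrase "present in >80 % of the sites on average" admits a
second reading (a per-site sample fraction); `classify_widespread(mode =
"sample_fraction")` implements it, and neither mode is asserted to be the
sole correct interpretation. The `site` column doubles as the plant-species
label for the per-species rules, so one table format serves both screens.

## What the simulators state, and what they do not

The generators' defaults are a *stated world*, not knobs: they were fixed
before the recovery thresholds were evaluated and are not tuned to test
outcomes.

* **Abundance** (`simulate_abundance`): log-normal latent-factor model.
  Strains in module *m* share a per-sample factor `N(0, module_sd = 1)`
  plus a module-level plant-enrichment effect on root/shoot samples;
  per-strain baselines `N(0, 1)`; log-scale noise `N(0, noise_sd = 0.3)`.
  Log-normality matches the positivity and skew of relative abundances and
  makes the mean-standardization step meaningful; noise 0.3 is a visible
  but not overwhelming within-module scatter at which the stated ARI ≥ 0.9
  recovery criterion must (and does) hold. With `noise_sd = 0` module rows
  are exactly proportional, hence pairwise r = 1.
* **Pangenome** (`simulate_pangenome`): ~1-kb genes laid on one scaffold
  per genome with 100–400 bp intra-run gaps; the hotspot block contiguous
  on the reference; each decoy separated from every other clade-specific
  gene by more than the gap threshold, so the gap rule must reject it;
  background genomes carry no clade-unique orthogroup (prevalence 0,
  trivially < 5 %). Boundary prevalences (8/175 vs 9/175) are exercised by
  directly constructed tables in the tests rather than by the generator.
* **Phenotypes** (`simulate_phenotypes`): `Normal(mean, sd)` truncated at
  0; default SD 0.5 cm — plate-level replication of root-elongation
  measurements plausibly spreads by about half a centimetre, and no
  variance model is available to emulate. The no-bacteria control defaults
  to 7 cm, an unconstrained healthy primary root on vertical agar after
  ~12 d.
* **Expression** (`simulate_expression`): null genes iid `N(0, 1)`, the
  marker set shifted by `delta` in the second treatment — the minimal world
  in which the resampling test's size and power are interpretable.
* **Survey** (`simulate_survey`): planted core ASVs are detected (RA
  ~ 0.05–5 %, far above 0.01 %) in every sample; every non-core ASV is
  deterministically excluded from one site, making exact core recovery a
  construction guarantee rather than a high-probability event;
  sub-threshold trace abundances are sprinkled in to exercise the strict
  presence rule.

A green recovery test therefore establishes that the implementation applies
the stated rules correctly on data that satisfy the rules' assumptions. It
does **not** establish performance on real communities: the abundance model
has no compositional closure, no zero inflation, no phylogenetic
correlation; the pangenome has single-scaffold genomes, no paralog bursts,
no annotation error; root lengths have no plate or experiment batch
effects; expression has no gene–gene correlation (which widens the
resampling null in real data); surveys have no depth variation across
samples. Those realities are exactly why the thresholds above are exposed
as parameters rather than constants.

## Numerical and degenerate-input conventions

* Argument errors are classed (`syncomr_arg_error`) and name the offending
  strain/gene/group; zero-variance rows are errors, never silently imputed.
* All generators take an explicit `seed`, use one RNG stream, restore the
  caller's RNG state, and are byte-identical on repeated calls.
* Permutation p values are never 0; hypergeometric tails use
  `phyper(x − 1, ..., lower.tail = FALSE)`; BH is `p.adjust(method = "BH")`,
  cross-checked against a step-up oracle.
* Empty inputs (empty table, empty hotspot list, zero planted markers) are
  defined results or named errors, never silent empties — see the examples
  in the function documentation.

## Known limitations

* No automatic choice of the module number `k`, by design.
* Orthogroup inference, VST/DEG calling, ordination/diversity analysis and
  image-based phenotype extraction are out of scope; their outputs are this
  package's inputs.
* The reversion test pools experiments; a mixed-model or stratified
  analysis is left to the caller's table filtering.
* `hotspot_report` presence/absence binarizes at ≥ 1 orthogroup carried; a
  profile-scan-based presence (HMM hits) would differ near the boundary.
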