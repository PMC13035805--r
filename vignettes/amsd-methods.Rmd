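---
title: "Methods: the aggregate mutation spectrum distance test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the aggregate mutation spectrum distance test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amsd)
```

## The model and its assumptions

A mutation spectrum is a count vector over a fixed channel schema; the
built-in schema is SBS96, the 96 single-base substitutions classified by
substituted pyrimidine, replacement base, and 5'/3' flanking bases
(purine-reference SNVs are reverse-complemented before classification).
Given two groups of per-sample spectra, the aggregate mutation spectrum
distance (AMSD) test asks whether the groups' *aggregate* spectra are
further apart than random partitions of the pooled samples would produce.

The test makes no assumption about which mutational processes generate the
spectra — that is its point. Its null hypothesis is exchangeability of
samples across groups: under the null, any relabeling of the pooled
samples is equally likely, so the permutation p-value is exact up to Monte
Carlo error. It assumes samples are independent; clustered designs
(multiple tumors per animal, recurrent samples per patient) would need
stratified permutation, which is out of scope here.

## Aggregation weighting

Two aggregation modes exist because they test subtly different things:

* `mean` (default) — average of per-sample frequency vectors. Every sample
  counts equally; outlier hypermutated samples cannot dominate. Recommended
  for detecting consistent group-level differences.
* `sum` — summed raw counts. Samples are weighted by mutation load; this is
  appropriate when the question is whether mutation-rich outliers are
  over-represented in one group.

Cosine distance is scale-invariant, so the sum aggregate needs no
normalisation. Under mean weighting an all-zero sample has no frequency
vector; such samples are dropped with a warning (screens of real cohorts
should pre-filter low-count samples anyway, e.g.
`filter_min_mutations(m, 10)`). Sum mode keeps them; they contribute
nothing.

## The permutation engine and p-value conventions

Each permutation reassigns the pooled samples into pseudo-groups of the
original sizes uniformly at random without replacement; splits are drawn
independently across permutations, so duplicate splits can occur (the
standard Monte-Carlo scheme). The engine is vectorised: the `n_perm`
splits form a 0/1 indicator matrix, one matrix product yields every
pseudo-group aggregate, and distances are computed row-wise. That makes
1000 tests of 1000 permutations each (the calibration study below) run in
about a minute.

Two p-value conventions are provided:

* `fraction_ge` (default): `p = #{d_null ≥ d_obs}/n_perm`. With zero
  exceedances the stored value is 0 with a `p_floored` flag, printed as
  `< 1/n_perm`; this matches the common reporting style for permutation
  screens (a result at 100,000 permutations reported as 3×10⁻⁵ means 3
  exceedances).
* `plus_one`: `(k+1)/(n_perm+1)`, the conservative estimator that counts
  the observed labeling as a permutation and is never 0; this is the right
  choice for calibration claims, and it is what the type-I error analysis
  uses.

Ties are counted as exceedances ("greater than or equal"), with distances
compared after a 1e-12 tolerance so that numerically identical splits are
never separated by floating-point noise. `amsd_exhaustive()` enumerates
all `choose(nA+nB, nA)` splits exactly once (capped, default 10,000
splits) and serves as the small-sample oracle; Monte-Carlo p-values are
required by the test suite to agree with it within three binomial
standard deviations at 50,000 permutations.

The two groups enter symmetrically, mean-mode results are invariant to
rescaling any sample's counts, and results are deterministic given a
seed. The distance is pluggable through a small registry (cosine is the
default and the only metric used in the analyses; Euclidean is included
as an example plug-in); any symmetric non-negative metric on non-negative
vectors fits the contract.

## The cohort simulator

`simulate_cohort_pair()` emulates a carcinogen-exposure design: control
samples draw exactly `B` mutations from a baseline mixture of signatures
(one multinomial per sample); exposed samples draw the same `B` baseline
mutations plus `round(f·B)` extra mutations from a single exposure
signature (so `f = 0.02`, `B = 2500` gives 50 extra mutations, and the
exposure signature's true exposure fraction in an exposed sample is
`f/(1+f)`). Defaults follow a two-tier design: `B = 50` emulates
whole-exome loads and `B = 2500` whole-genome loads; the baseline is 30%
`syn1` + 60% `syn2` + 10% `syn3`, emulating a clock-like/diffuse/oxidative
endogenous background.

Per-sample totals are fixed rather than Poisson-dispersed because the
design specifies exact per-sample loads; `round()` is R's round-half-even,
consistent with the 2% → 50 example. Counts are rounded once, at the
extra-mutation computation. The simulator does not model genomic
positions, trinucleotide opportunity (exome vs genome context abundance),
clonal structure, or inter-sample load variation — so passing power
figures say how the test behaves under clean multinomial sampling, not
under the extra dispersion of real cohorts, where power will generally be
somewhat lower at equal nominal parameters.

The synthetic catalog (`make_fixture_catalog()`) contains five signatures:
three backbones, one spiky signature (≥ 80% of mass on ≤ 4 channels,
APOBEC-like) and one flat signature (no channel above 3%). The spiky/flat
pair exists to express the detectability contrast: at low mutation loads a
concentrated exposure shifts a few channels far above sampling noise,
while a diffuse exposure spreads the same mutations thinly across ~96
channels, and AMSD power is correspondingly lower. The catalog is fully
synthetic; no published signature profile is reproduced.

## The signature-refitting baseline

The comparison baseline refits each sample against a signature catalog by
non-negative least squares (`pracma::lsqnonneg`), iteratively zeroing
signatures below a 5% exposure fraction and refitting until stable — a
documented, reproducible stand-in for assignment tools whose exact
settings are not reproducible; numerical equality with any specific
assignment tool is not claimed. Each signature present in any sample of
either group is then compared between groups by a two-sided Wilcoxon
rank-sum test (exact for small untied samples, normal approximation with
tie and continuity correction otherwise — `stats::wilcox.test`), p-values
are Bonferroni-corrected over the tested set, and the minimum corrected
p-value is the overall group-difference significance.

A design point that matters when evaluating this baseline: in practice the
fitting database is much larger than the set of processes truly active in
a cohort, and the baseline's two weaknesses — the Bonferroni burden of
many tested signatures and the instability of refitting in a large,
partially collinear search space — only appear under that condition.
Fitting simulated cohorts back against the same five-signature catalog
they were simulated from makes refitting artificially easy and the
baseline artificially strong. `make_fixture_fitting_catalog()` therefore
extends the core catalog with 15 synthetic decoy signatures (alternating
focused and diffuse profiles), and the method-comparison analyses fit
against this 20-signature catalog while simulating from the 5-signature
truth. At five samples per group the exact rank-sum test's smallest
achievable two-sided p is `2/choose(10,5) ≈ 0.0079`, so with eight or more
tested signatures the Bonferroni-corrected baseline cannot reach 0.05 at
all — the structural reason it underperforms AMSD on small cohorts, which
the test suite checks at `B = 2500`, `f = 0.2`, flat exposure, 50
replicates.

## Screening and multiple-testing machinery

`run_screen()` executes a plan of pairwise comparisons, skipping any
comparison where either group has fewer than 5 samples (configurable), and
adjusts p-values across executed comparisons only, by Bonferroni and
Benjamini–Hochberg (`stats::p.adjust`). For volcano plots that mix many
comparisons, a single BH significance line is estimated by regressing
`−log10(adjusted p)` on `−log10(raw p)` (OLS with a free intercept —
"linear regression" unqualified defaults to one, and the intercept
absorbs the offset the BH step-up induces) and drawing the line at
`−log10(0.05)·β`. Floored permutation p-values enter adjustment as
`1/n_perm` and are excluded from the regression, whose logs they would
otherwise make infinite. `fisher_exact_2x2()` uses the probability-mass
two-sided convention (the sum of all hypergeometric outcomes no more
probable than the observed table), the convention under which the two
published worked examples print as 0.2 and 0.02.

## Numerical choices and degenerate inputs

* Distance ties: compared at 1e-12 tolerance (above).
* NNLS pruning: if every signature falls below the 5% fraction, the
  largest single signature is retained rather than emptying the fit; the
  pruned refit's residual can only be ≥ the unpruned residual (asserted in
  the tests).
* Zero-count samples: error under mean aggregation if none remain after
  the drop policy; exposure fit returns all-zero exposures.
* Tallying: reference-mismatching records, sequence-edge positions,
  non-ACGT contexts and absent chromosomes are skipped and counted by
  reason, never fatal; soft-masked (lowercase) FASTA is uppercased first.
  Variant positions are 1-based (VCF/MAF convention).
* Spectrum files: the first column header may be `MutationType`, `Type`
  or empty; rows in any order are reordered to schema order; missing
  schema channels are an error unless `fill_missing = TRUE` zero-fills.

## Problem sizes used by the test suite

The suite and acceptance script scale the simulation studies to: type-I
error calibration at 1000 null cohorts (`B = 2500`, `n = 25`) × 1000
permutations; the power grid at `B ∈ {50, 2500}`, `f ∈ {0.02, 0.2}`,
`n ∈ {5, 25, 125}`, 50 replicates per cell; oracle-equivalence checks at
50,000 permutations on cohorts of ≤ 8 samples. These sizes give binomial
standard errors small enough for the orderings being asserted (≈ 0.03 on
a power of 0.5 at 50 replicates) while keeping the full suite under a few
minutes; power monotonicity in `n` and `f` is asserted allowing at most
one violation exceeding two standard errors of the difference, since at
50 replicates adjacent cells near the floor or ceiling are within noise
of each other.

## Known limitations

* No stratified or blocked permutations, covariate adjustment, or
  omnibus (> 2 group) tests.
* The tallier covers SBS96 only; other channel systems (DBS, indel, CNV,
  SV) are accepted as generic matrices in a declared schema but not
  constructed from raw calls.
* No exome/genome opportunity rescaling in either the simulator or the
  refitter.
* The refitter is deliberately simple (NNLS + pruning); it is a baseline
  for method comparison and an interpretation aid, not a
  state-of-the-art assignment tool.
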