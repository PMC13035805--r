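# amsd — aggregate mutation spectrum distance permutation testing

Somatic mutation spectra — the distribution of a sample's single-base
substitutions over the 96 trinucleotide-context channels (SBS96) — shift
when a mutational process is gained, lost, or rebalanced. Signature
deconvolution describes *which* processes are active, but it does not by
itself answer the comparative question most studies actually ask: *do two
groups of samples (exposed vs control, one ancestry vs another) differ in
their mutation spectra at all?*

`amsd` answers that question with a signature-agnostic permutation test.
For groups *A* and *B* of per-sample spectra, it forms one aggregate
spectrum per group — by default the mean of per-sample frequency vectors
(each sample weighted equally), optionally the summed counts (mutation-rich
samples weigh more) — and computes the cosine distance between the
aggregates,

```
d(A, B) = 1 − (a · b) / (‖a‖ ‖b‖),   a = mean_i a_i / |a_i|₁,  b likewise.
```

Significance comes from relabeling: samples are pooled and reshuffled into
pseudo-groups of the original sizes, the aggregate distance is recomputed
for each of `n_perm` reshufflings, and

```
p = #{ d_null ≥ d_obs } / n_perm          ("fraction_ge", the default)
p = (#{ d_null ≥ d_obs } + 1)/(n_perm+1)  ("plus_one", never exactly 0)
```

The package also provides the machinery around the test: SBS96 tallying of
SNVs against a reference genome (pyrimidine-centred strand collapse),
COSMIC-dialect spectrum/catalog I/O, a signature-mixture cohort simulator
for power analysis, non-negative least-squares exposure refitting with 5%
pruning plus the per-signature Wilcoxon rank-sum comparison baseline,
multi-comparison screening with Bonferroni/Benjamini–Hochberg correction
and the regression-estimated BH plotting threshold (`−log10(0.05)·β`), a
Fisher's-exact 2×2 utility, and an `amsd` command-line interface.

## Worked example

Simulate a 25-vs-25 cohort pair from a synthetic signature catalog: both
groups share an endogenous baseline (30% `syn1`, 60% `syn2`, 10% `syn3`,
2500 mutations per sample), and the exposed group gains 10% extra mutations
(250) from a concentrated APOBEC-like signature:

```r
library(amsd)

catalog  <- make_fixture_catalog(seed = 1)
baseline <- mixture_spec(c(syn1 = 0.3, syn2 = 0.6, syn3 = 0.1))
pair <- simulate_cohort_pair(
  simulation_spec(baseline_mutations = 2500, exposure_signature = "synSpiky",
                  exposure_fraction = 0.1, samples_per_group = 25, seed = 7),
  baseline, catalog)

amsd_test(pair$control, pair$exposed, n_perm = 10000, seed = 42)
#> AMSD permutation test
#>   groups: 25 vs 25 samples; weighting = mean; distance = cosine
#>   observed distance = 0.0601937
#>   p = < 0.0001 (0 of 10000 null distances >= observed)
```

The observed aggregate cosine distance (0.060) exceeds every one of the
10,000 relabeled distances, so the spectrum shift is significant at the
reporting floor of the permutation resolution (p < 1/10000; use
`p_convention = "plus_one"` for the conservative estimator 1/10001).
Refitting exposures then identifies the driver:

```r
e <- fit_exposures_nnls(pair$exposed, catalog)
round(colMeans(exposure_fractions(e)), 3)
#>     syn1     syn2     syn3 synSpiky  synFlat
#>    0.274    0.531    0.090    0.091    0.014
```

The spiked signature is recovered at a mean exposure fraction of 0.091
(truth: 0.1/1.1 = 0.0909), and `wilcoxon_signature_comparison()` flags it
as the most significant per-signature difference. `plot_amsd_null()` draws
the null histogram; `run_screen()` scales the test to many comparisons
with multiple-testing correction.

The same workflow is available from the shell via the installed `amsd`
script (`amsd fixtures`, `amsd tally`, `amsd test`, `amsd screen`,
`amsd simulate`, `amsd fit`, `amsd compare-signatures`, `amsd volcano`);
every run writes a JSON manifest sufficient to reproduce it.

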