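Package: amsd
Title: Aggregate Mutation Spectrum Distance Permutation Testing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects significant differences between groups of somatic
    mutation spectra with the aggregate mutation spectrum distance (AMSD)
    permutation test: spectra within each group are aggregated (mean of
    per-sample frequency vectors, or summed counts) and the cosine distance
    between the two aggregates is compared against a null distribution
    obtained by random relabeling of samples. Includes SBS96 trinucleotide
    context tallying from variant calls against a reference genome, a
    signature-mixture cohort simulator for power analysis, non-negative
    least squares signature refitting with a per-signature Wilcoxon
    rank-sum comparison baseline, and multi-comparison screening with
    Bonferroni and Benjamini-Hochberg correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    pracma,
    ggplot2,
    optparse,
    Biostrings
Suggests:
    vcfR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
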