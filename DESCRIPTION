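Package: introtopo
Title: Topology Weighting, Block-Permutation Introgression Tests and
    Allele-Sharing Statistics for Mimicry Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing localized adaptive introgression at color-pattern
    loci in co-mimetic butterfly species, and for the population-genomic
    statistics that surround such tests. Builds neighbor-joining genealogies in
    nonoverlapping 100-SNP windows from phased haplotypes, summarizes each
    window by quartet topology weights, and tests for an excess of
    introgression-compatible windows (the intro95 count) in a focal region with
    a 100-kb block-permutation null. Also provides f4 statistics with a
    weighted 500-kb block jackknife, windowed fd/fdM introgression scans,
    invariant-site-aware pooled nucleotide diversity, a rule-based
    trans-species polymorphism classifier, genome-wide association
    post-processing (site filters, Bonferroni threshold, Spearman rho-squared
    scoring, fully-associated intervals, genotype-matrix export, diagnostic
    k-mer motif scan), and a multispecies coalescent simulator with an
    introgressed tract that generates phased test data end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
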