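Package: msatclone
Title: Clonal Lineages and Population Structure from Microsatellite Genotypes
Version: 0.1.0
Authors@R:
    person("msatclone", "developers", email = "msatclone@example.org",
           role = c("aut", "cre"))
Description: Analysis of multilocus diploid microsatellite genotypes from
    partially clonal marine invertebrates such as reef corals. Provides
    readers and writers for the GenAlEx, STRUCTURE and Genepop genotype
    dialects, multilocus-lineage (clone) assignment under a one-mismatch
    rule with a clonality index, per-locus diversity statistics with
    Hardy-Weinberg and linkage-disequilibrium testing under
    false-discovery-rate control, F_ST with a permutation test, a
    from-scratch admixture-model Bayesian clustering Gibbs sampler with
    Evanno delta-K model choice and replicate-run merging, discriminant
    analysis of principal components, simple-sequence-repeat discovery in
    assembled sequences, and a synthetic-data generator with planted truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
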