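Package: introkit
Title: Detecting Interspecies Introgression from RAD-Seq Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable re-implementation of a population-genomic
    introgression-detection workflow for sympatric stickleback species:
    genotype filtering of multi-sample VCFs, neighbor-joining clustering on
    Euclidean genotype distances, Bayesian admixture-proportion estimation
    with a Gibbs/Metropolis sampler (admixture ancestry with correlated
    allele frequencies), outgroup-polarized ABBA-BABA D-statistics with
    block-jackknife Z-scores, an alignment mismatch-rate contamination
    check, and design of transposable-element diagnostic PCR markers placed
    in read-coverage gaps. A synthetic-data generator (Balding-Nichols
    population divergence, SAM read simulation, coverage tracks) provides
    known truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vcfR,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
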