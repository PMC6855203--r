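Package: crossase
Title: Crossbred Heterozygosity Simulation, Trio Phasing and
    Allele-Specific Expression Calling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for breed-of-origin analysis in three-way crossbred
    livestock. Computes the per-locus probability that a simulated
    crossbred offspring is heterozygous (PHS) from purebred genotype
    frequencies for arbitrary crossbreeding schemes, phases offspring
    heterozygous SNPs by trio genotypes, and calls allele-specific
    expression (ASE) per gene from phased exonic allelic read counts
    using an exact binomial test with Bonferroni correction. Includes a
    synthetic-data generator (hierarchical Balding-Nichols breed
    frequencies, a tracked three-way pedigree with ground-truth allele
    origins, and negative-binomial allelic RNA counts with planted ASE
    effects) so every step can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
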