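Package: parabsa
Title: Bulk Segregant Analysis Through the Fungal Parasexual Cycle
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis toolkit for mapping classical mutations
    in asexual filamentous fungi by parasexual bulk segregant analysis.
    Models diploid formation from complementary-marked haploid parents,
    haploidization by whole-chromosome loss with rare mitotic crossover,
    phenotype derivation and trait-based pooling; simulates pooled-sequencing
    depth and allele counts; applies frequency/coverage variant validation,
    a pool SNP-conservation scan with coding-effect annotation and candidate
    ranking; and performs classical two-point marker linkage analysis
    (parental/nonparental segregant counts and recombination frequencies).
    Includes a deterministic synthetic study fixture reconstructing an
    eight-chromosome cross with 52 inter-parental SNPs and a 78-member
    trait pool.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    yaml,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse
Config/testthat/edition: 3
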