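Package: hapsweep
Title: Detection and Classification of Soft and Hard Selective Sweeps from
    Phased Haplotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Haplotype-cluster statistics (iHSL, RiHS and the composite
    RiHSL) for detecting incomplete selective sweeps from phased, polarized
    haplotype data, together with a simulation-based nearest-neighbour
    classifier that distinguishes soft from hard sweeps and a soft-shoulder
    region correction.  Includes the comparator statistics iHS, nSL and
    H12/H2H1, a rescaled forward Wright-Fisher sweep simulator with a
    coalescent neutral backend, and power/false-positive-rate/localization
    benchmarks.  Input formats: phased VCF with ancestral-allele
    annotation, ms-format haplotype blocks, and genetic maps with linear
    interpolation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    IRanges,
    GenomicRanges,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
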