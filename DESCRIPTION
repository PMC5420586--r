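Package: binQTL
Title: Bin-Marker Linkage Maps and QTL Mapping for Low-Coverage F2 Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building recombination-bin genetic maps from noisy
    genotyping-by-sequencing (GBS) calls in biparental F2 populations and for
    mapping quantitative trait loci (QTL) on them. Implements segregation-pattern
    classification and chi-square distortion filtering of SNP markers, the
    15-SNP sliding-window consensus genotype caller with 100-kb recombination-bin
    construction, Kosambi genetic map estimation from maximum-likelihood
    recombination fractions, composite interval mapping (CIM) with an EM mixture
    likelihood and permutation thresholds, LASSO multi-locus scans with
    post-selection tests, and descriptive phenotype/correlation reports with
    QTL-interval gene lookup. A synthetic F2 population generator with a GBS-like
    observation-noise model makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    vcfR,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
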