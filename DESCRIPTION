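Package: shellBSA
Title: Bulked-Segregant Analysis and Whole-Shell Thickness Phenotyping for
    Pod-Shell QTL Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping quantitative trait loci for pod shell
    thickness (and similar pooled-extreme designs) from bulked-segregant
    sequencing data. Implements four per-variant association statistics
    (delta SNP-index, pooled allele-frequency Euclidean distance, the
    G log-likelihood-ratio statistic with tricube physical-distance
    smoothing, and Fisher's exact test), 2-Mb/10-kb sliding-window
    smoothing, simulation- and quantile-based confidence thresholds, and
    four-method candidate-region intersection with gene annotation.
    Also provides a contour-based whole-shell thickness measurement from
    binary cross-section masks, and a synthetic-data generator (F2
    genotypes, extreme-phenotype bulks, pooled read depths, annulus-like
    shell masks) with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    grDevices,
    utils,
    png,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
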