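Package: ancestryMosaic
Title: Chromosome-Scale Ancestry Mosaics from Pooled Allele Frequencies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying how evolutionary histories vary among
    chromosomes in admixed species complexes. Implements admixture-graph
    fitting on population allele-frequency covariance matrices with a
    per-chromosome tree-likeness statistic (the proportion of covariance
    explained, PCVE), sliding-window four-taxon topology scores from
    polarized coded alleles, a SNP-permutation test for among-chromosome
    tree heterogeneity based on the generalized (clustering-information)
    Robinson-Foulds distance, and partitioning of additive genetic variance
    among chromosomes from per-SNP effect estimates. Includes a
    ground-truth-known simulator of pool-seq allele counts generated under
    chromosome-specific admixture graphs, plus a sparse polygenic trait
    simulator, so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    ape,
    phangorn,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
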