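Package: gcgwas
Title: Multi-Trait GWAS for Growth-Curve Parameters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits nonlinear growth models (Brody, von Bertalanffy, Logistic,
    Gompertz, Richards) to longitudinal weight-age records, treats the
    per-animal parameter estimates (mature weight A, integration constant b,
    maturity rate K) as phenotypes in a three-trait single-SNP mixed model
    with a pedigree polygenic effect, partitions marker-attributed genetic
    variance across SNPs and Gabriel-style haplotype blocks, and validates
    QTL-detection power on simulated full-sib populations. Includes genotype
    quality control (call rate, MAF, Hardy-Weinberg exact test),
    eigendecomposition-accelerated multivariate EM-REML, Benjamini-Hochberg
    FDR control, nearest-gene annotation against a local gene table, and a
    full synthetic-data generator (pedigrees, genotypes with Haldane
    recombination, planted QTL, polygenic covariance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    ggplot2,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    jsonlite
Config/testthat/edition: 3
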