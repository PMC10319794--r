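Package: jpegwas
Title: Joint Additive-Dominant GWAS and Genomic Prediction Across Inbred
    Parents and Hybrid Testcrosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the JPEG (Joint analysis of Phenotypes, Effects, and
    Generations) pipeline for hybrid-crop genetics. Inbred-parent phenotypes
    (V), hybrid-testcross phenotypes (T), general combining ability (G), and
    mid-parent heterosis (H) are standardized and stacked into a single
    response that is scanned with an iterative multi-locus general linear
    model for both additive and dominant SNP effects. Significant SNPs are
    merged into loci and classified as additive, dominant, or both. The
    package also builds VanRaden additive and dominance kinships, estimates
    additive and dominant variance components and heritabilities by REML,
    and predicts hybrid performance by gBLUP or by detected-locus models
    under repeated twofold cross-validation. A diallel testcross simulator
    with planted additive and dominant QTLs provides a full test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    Matrix,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
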