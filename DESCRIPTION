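Package: dormqtl
Title: QTL Mapping of Seed Dormancy from Bin Maps of Rice Substitution
    and Backcross Inbred Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to dissect the genetic basis of rice seed dormancy with
    chromosome segment substitution line (CSSL) and backcross inbred line
    (BIL) populations. Implements recombination bin-map construction from
    SNP genotypes by sliding-window smoothing, germination-curve trait
    extraction (G3d, G7d, T50, AUC), a ridge-regression genome scan with
    permutation p-values, LMG variance decomposition of declared QTLs,
    cross-trait clustering of QTLs into seed-dormancy regions, F2
    single-marker validation statistics, and two-locus epistasis ANOVA.
    A population simulator with planted QTL effects on latent germination
    parameters provides ground truth for end-to-end recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    vcfR
Suggests:
    car,
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
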