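Package: polyarch
Title: Polygenic Architecture Estimation and Risk Projection from GWAS
    Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits normal-mixture effect-size distributions to genome-wide
    association study (GWAS) summary statistics to estimate polygenicity and
    GWAS heritability on the log-odds-ratio scale, and projects the yield of
    future GWAS: expected discoveries, genetic variance explained, achievable
    polygenic risk score (PRS) variance at genome-wide-significant or
    optimized p-value thresholds, discriminatory accuracy (AUC), relative
    risk in the upper PRS tail, and absolute residual lifetime risk under
    competing mortality.  Includes a synthetic summary-statistics generator
    with block-diagonal LD, the standard four-step quality-control pipeline
    (panel restriction, per-SNP sample-size filter, MHC exclusion, clumping
    of large-effect loci), and a configuration-driven report pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
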