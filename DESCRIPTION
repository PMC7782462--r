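Package: dhgs
Title: Genomic Prediction for Early-Stage Maize Doubled-Haploid Testcross Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools to study genomic selection in the first stage of a maize
    doubled-haploid (DH) testcross breeding program.  Simulates multi-year DH
    programs (biparental populations with controlled full-sib/half-sib overlap
    across years, dominant presence/absence markers, multi-location yield
    trials in incomplete blocks); builds genomic relationship matrices from
    dominant markers after minor-allele-frequency filtering; computes
    stage-one line BLUPs and broad-sense heritabilities; fits
    single-environment and reaction-norm multi-environment GBLUP models with
    a built-in Gibbs sampler; and evaluates training/testing designs
    (fivefold cross-validation, across-year prediction, size-adjusted
    training sets, sibship-partitioned sets, and partial conversion of the
    testing population).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
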