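Package: periomr
Title: Bidirectional Two-Sample Mendelian Randomization for Periodontitis
    and Kidney Function
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for bidirectional two-sample Mendelian randomization (MR)
    from GWAS summary statistics, built around the analysis of chronic
    periodontitis and kidney-function biomarkers (estimated glomerular
    filtration rate and blood urea nitrogen). Provides summary-statistics
    input/output and allele harmonization, instrument selection (association
    threshold, confounder blocklist, LD clumping, Steiger directionality
    filtering), the Wald ratio, inverse-variance-weighted (fixed and
    multiplicative random effects), weighted-median and MR-Egger estimators
    with Cochran's Q and the Egger intercept pleiotropy test, power
    calculations, forest/scatter report tables, a synthetic summary-statistics
    generator with known causal structure, and the periodontitis/kidney GWAS
    instrument tables as built-in fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
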