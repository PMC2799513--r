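Package: lesionsig
Title: DNA Damage Quantification and Genotoxic Expression Signatures in Blood
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies mitochondrial and nuclear DNA damage from
    long-amplicon quantitative PCR using the Poisson zero-class model,
    performs two-class unpaired SAM-style permutation differential
    expression, gene-set scoring by the GSA maxmean statistic with
    restandardization, consensus genotoxic-signature construction with
    direction-matched hypergeometric overlap, co-expression pattern
    extraction (EPIG), and clinical-covariate association (delta-Ct
    relative quantification, univariate linear models, q-values,
    supervised correlation, median-age dichotomization). Includes a
    synthetic-cohort generator with known planted truth so every stage
    is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
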