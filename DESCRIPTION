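Package: sigsurr
Title: Constrained Resampling Tests for the Biological Meaning of
    Prognostic Gene Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for interrogating whether prognostic gene-expression
    signatures carry interpretable biological meaning. Random gene sets are
    sampled from pools constructed by systematically removing a signature's
    genes and, iteratively by ontology hierarchy level, all genes annotated
    to the signature's biological-process terms. Each sampled set is scored
    by first-principal-component median-split stratification of patients
    followed by a Kaplan-Meier/log-rank survival comparison, yielding the
    frequency of "surrogate" gene sets: random sets that predict outcome as
    well as the signature while sharing none of its ontology annotations.
    Includes analytic bounds on the number of such surrogate sets, signature
    collection statistics, a falsification test for signature
    interpretability, and a synthetic-data generator emulating the
    statistical structure of breast-cancer survival cohorts.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
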