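Package: fagwas
Title: Case-Control GWAS and HLA Fine-Mapping for Self-Reported Food Allergy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully testable re-implementation of a two-sampleset
    food-allergy association pipeline: variant quality control, principal
    component analysis with outlier removal, identity-by-descent duplicate
    detection, per-food additive logistic GWAS with principal-component
    covariates, bi-directional discovery-evaluation candidate selection,
    inverse-variance fixed-effects meta-analysis, conditional association with
    the r2-equivalent statistic, Relative Predispositional Effects (RPE)
    analysis of multi-allelic HLA allele and haplotype count tables, eQTL
    overlap filtering with the relative-signal-strength statistic, and a
    food cross-reactivity matrix. A truth-annotated synthetic cohort
    generator provides verifiable inputs for every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
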