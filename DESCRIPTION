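Package: exoburden
Title: Exome Variant Prioritisation and Gene-Panel Burden Analysis for
    Hearing-Loss Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested implementation of a rare-variant prioritisation
    cascade for annotated exome cohorts: a site-quality gate, a minor
    allele frequency gate with population fallback, a consequence-severity
    gate, and tiered pathogenicity classification by in-silico predictor
    voting (majority, unanimous, loss-of-function-only). Downstream cohort
    analyses compute per-individual disease-gene burden against curated
    panels, genes shared by all members of a phenotype subgroup, genes and
    identical variants recurrent across individuals, apparently-homozygous
    very rare variants, and multi-variant (candidate compound
    heterozygous) genes. A synthetic annotated-cohort generator with a
    full truth table makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
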