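Package: icclock
Title: DNA Methylation Clock for Intrinsic Capacity
Version: 0.1.0
Authors@R:
    person("ICclock", "Developers", email = "icclock@example.org", role = c("aut", "cre"))
Description: Computes the composite intrinsic capacity (IC) score from five
    clinical domains (cognition, locomotion, psychological, sensory, vitality),
    trains and applies an elastic-net DNA-methylation predictor of IC ("IC
    clock"), and runs the downstream analyses that characterize such a clock:
    two-phase age-of-decline regression, reference-based leukocyte
    deconvolution, transcriptome-wide association with age-adjusted DNAm IC,
    gene-set enrichment, Cox proportional-hazards mortality models with
    Kaplan-Meier and restricted-mean survival contrasts, and health/lifestyle
    association screens. A synthetic-cohort generator with planted ground
    truth makes every stage testable without access to controlled cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    survival,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
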