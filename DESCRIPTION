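Package: splitplotDE
Title: Split-Plot Differential Expression Across Tissues in a Two-State Design
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Differential-expression analysis for balanced multi-tissue
    repeated-measures expression studies in which subjects (RNA pools) from two
    physiologic states are each assayed in several tissues. Implements
    detection-based gene filtering from exon-level detection p-values, per-gene
    balanced split-plot ANOVA with compound-symmetry covariance (main effects,
    within-tissue simple effects, method-of-moments variance components,
    untransformed fold ratios), dual-threshold differential-expression calls
    with proportion-of-false-positives estimation and q-values, signed
    weighted-integer cross-tissue pattern coding, right-tailed Fisher's exact
    gene-set overrepresentation, stability-based reference-gene selection, and
    a seeded synthetic-study generator with a ground-truth ledger for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    lme4,
    lmerTest,
    emmeans
Config/testthat/edition: 3
RoxygenNote: 7.3.3
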