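Package: stressmeta
Title: Random-Effects Meta-Analysis of Chronic-Stress Transcriptomic Contrasts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cross-laboratory meta-analysis of differential-expression results
    from chronic-stress studies of the rodent prefrontal cortex. Parses
    per-contrast differential-expression tables, collapses probe-level rows to
    gene-level log2 fold changes with standard errors, aligns genes across
    contrasts, fits a per-gene intercept-only random-effects model
    (REML between-study variance, inverse-variance pooling, Wald inference)
    with Benjamini-Hochberg false-discovery-rate correction, runs preranked
    gene-set enrichment on the pooled effect sizes, and compares the resulting
    differentially expressed genes against external studies through
    one-to-one ortholog mapping. Includes a synthetic-data generator that
    emulates the multi-dataset, multi-platform study design with known ground
    truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, yaml
Suggests: testthat (>= 3.0.0), metafor, fgsea, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
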