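Package: stresspan
Title: Stress Resistance and Longevity Analysis for Long-Lived C. elegans Mutant Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking stress resistance to longevity across panels of
    long-lived Caenorhabditis elegans mutants. Provides survival-analysis
    primitives for lifespan and stress assays (Kaplan-Meier estimation,
    restricted mean survival, log-rank and Gehan-Breslow-Wilcoxon tests,
    Dunnett-adjusted control-vs-many comparisons), strain-level phenotype
    summaries (lifespan extension, per-assay resistance endpoints and
    direction calls, normalized combined stress scores, resistance counts),
    phenotype-lifespan regression, per-gene expression-phenotype correlation
    across strains, observed/expected gene-set overlap enrichment with
    hypergeometric significance, generic over-representation analysis over
    GMT term maps, a minimal count-normalization and differential-expression
    stage with batch adjustment, and a synthetic-cohort generator with
    planted ground truth so the full pipeline can be validated by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival,
    multcomp,
    optparse
Config/testthat/edition: 3
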