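Package: snpmeta
Title: Meta-Analysis of Case-Control Genotype Counts for Genetic
    Association Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pools case-control genetic association studies from per-study
    genotype counts. Collapses three-genotype tables into 2x2 tables under
    the five standard genetic contrasts (recessive, dominant, two codominant
    comparisons, allele), estimates per-study odds ratios with Woolf
    log-scale variances and Haldane-Anscombe continuity correction,
    and combines them by inverse-variance fixed-effect, Mantel-Haenszel,
    or DerSimonian-Laird random-effects pooling with Cochran's Q
    heterogeneity test driving automatic model selection. Includes
    subgroup analysis, leave-one-out sensitivity analysis, the
    Begg-Mazumdar rank-correlation test for publication bias with funnel-plot
    data, a bundled corpus of published CRP polymorphism studies, and a
    Hardy-Weinberg genotype-count simulator with known effect sizes,
    between-study heterogeneity and selective-publication mechanisms for
    validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
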