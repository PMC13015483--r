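Package: exermap
Title: Repeated-Measures Multi-Omic Analysis of Acute Exercise Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Statistical machinery for repeated-measures multi-omic studies
    of acute exercise: difference-in-changes ("delta-delta") differential
    analysis with per-feature random-intercept mixed models and Satterthwaite
    tests, a simulation harness that evaluates candidate longitudinal
    strategies (paired t, OLS, weighted/unweighted mixed models, unstructured
    GLS, GEE-AR1 with sandwich errors) on moment-matched non-normal data,
    competitive pre-ranked set testing (CAMERA-PR) and hypergeometric
    over-representation analysis, signed weighted co-expression modules with
    eigengene-trait biweight midcorrelation, fuzzy c-means trajectory
    clustering with zero-baseline scaling, and secreted-factor endocrine
    connectivity (Ssec) scoring across tissue pairs. Includes synthetic-data
    generators that plant every structure the pipeline assumes, so the whole
    workflow is testable on a laptop with no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    edgeR,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    e1071,
    optparse,
    mclust,
    fgsea,
    jsonlite,
    limma,
    lme4,
    lmerTest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
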