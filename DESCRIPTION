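Package: nicheshift
Title: Niche Dynamics and Reciprocal Distribution Modelling for Biological Invasions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects realized-niche shifts of invasive species between a native
    and an invaded range. Builds a shared environmental ordination space (PCA on
    pooled background climates), kernel-density occupancy surfaces corrected for
    environment availability, Schoener's D niche overlap with equivalency and
    similarity permutation tests, and the expansion / maximum-niche-stability /
    unfilling decomposition of the COUE framework restricted to analogue
    climates, including yearly niche dynamics and a marginality-quantile sweep.
    A reciprocal ensemble species distribution modelling stage (boosted trees,
    random forests, and a regularized presence-background logistic surrogate for
    maximum entropy) produces majority-vote consensus maps, MESS novel-climate
    screens and a four-category invasion-risk overlay. A synthetic-scenario
    generator with a controllable true niche shift, introduction point and
    yearly radial spread provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    randomForest,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    pROC,
    rmarkdown,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
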