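Package: nbfsbench
Title: Benchmarking Feature Selection and Classification on Negative Binomial Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation benchmark of feature-selection algorithms for
    sequencing-style count data. Generates case/control negative binomial
    count matrices over a grid of signal-to-noise ratios, means and
    dispersions; implements from scratch the negative binomial
    differential-expression machinery (median-of-ratios size factors,
    conditional maximum-likelihood common and tagwise dispersion
    estimation, a pooled mean-variance local regression, the conditional
    exact test, and a two-model empirical-Bayes posterior); wraps rank-sum,
    lasso, particle-swarm decision-tree and random-forest selectors behind
    a uniform interface; evaluates type-I error, power, sensitivity and
    specificity over replications; runs repeated stratified cross-validated
    classification (logistic, RBF SVM, random forest); and mines frequent
    sets of deregulated features across cohorts with an Apriori miner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    parallel,
    withr,
    glmnet,
    randomForest,
    rpart,
    e1071,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
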