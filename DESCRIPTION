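Package: workloadbci
Title: EEG Mental-Workload Estimation Across Affective Contexts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A passive brain-computer-interface analysis pipeline for
    estimating mental workload (n-back task difficulty) from multichannel
    EEG, and for quantifying how well such a classifier transfers between
    affective contexts (psychosocial stress versus relaxation). Implements
    the oscillatory branch (filter-bank common spatial patterns with
    log-power features), the event-related-potential branch (regularized
    Fisher spatial filters on downsampled single-trial time courses),
    minimum-redundancy maximum-relevance feature selection, shrinkage
    linear discriminant analysis, block-wise stratified cross-validation
    schemes (general, within-, across-, and combined-context, and
    time-halves controls), majority-vote fusion with binomial chance
    levels, and a deterministic synthetic n-back EEG study generator with
    plantable workload and context effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp,
    RcppArmadillo
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
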