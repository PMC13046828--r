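Package: sdwheel
Title: Serial-Dependence Analysis of Facial-Identity Judgments on a Morph
    Wheel with ERP Counterparts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing serial dependence in facial-identity
    adjustment tasks on a circular morph continuum, together with the
    event-related-potential (ERP) analyses that accompany such designs.
    Provides circular index arithmetic on the morph wheel, the
    median-difference serial-dependence bias statistic with bootstrap
    confidence intervals, aligned-rank-transform repeated-measures ANOVA
    with BIC Bayes factors, ERP preprocessing contracts (re-referencing,
    zero-phase Butterworth low-pass, baseline correction), spatio-temporal
    cluster-based permutation tests with a compiled permutation kernel,
    vector-scaled topographic comparison, robust (IRLS) brain-behaviour
    regression, JZS paired Bayes factors, and a synthetic-data generator
    that emulates the full experimental design so the whole pipeline runs
    end-to-end without any recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    Rcpp,
    jsonlite,
    lme4,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
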