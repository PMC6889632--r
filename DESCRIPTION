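Package: phylallom
Title: Evolutionary Allometry on Ensembles of Time-Calibrated Fossil Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating evolutionary allometric trends from fossil
    measurement data while accounting for phylogenetic uncertainty. Base
    supertree topologies with unresolved polytomies are stochastically
    dichotomized and time-calibrated from stratigraphic tip age ranges under
    a birth-death-sampling model, producing an ensemble of candidate
    time-trees. On each tree a log-log regression of one skeletal measurement
    on another is fitted by phylogenetic generalized least squares under
    Brownian motion with simultaneous estimation of Pagel's lambda, under an
    Ornstein-Uhlenbeck model, or by ordinary least squares. Estimates are
    pooled across the tree ensemble by multiple-imputation (Rubin's) rules,
    and subclades deviating from the main allometric trend are detected by
    phylogenetic analysis of covariance with pooling of dependent p-values
    and an iterative exclusion loop. A synthetic-data generator with known
    ground truth supports end-to-end validation of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    nlme,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
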