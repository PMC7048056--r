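Package: nichecompare
Title: Comparative Analysis of Oral Microbial Niches from OTU Count Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for comparing bacterial communities across
    oral sampling niches (supragingival plaque, buccal mucosa, tongue dorsum,
    saliva) in a repeated-measures animal study. From an OTU-by-sample read
    count table with sample metadata it applies low-depth sample exclusion and
    rare-taxon grouping, fits per-taxon binomial generalised linear mixed
    models (logit link, crossed animal and sampling-day random intercepts) with
    within-animal permutation inference and Benjamini-Hochberg false discovery
    control, models Shannon diversity with a linear mixed model, performs
    animal-centred (multi-group) principal component analysis with bivariate
    confidence ellipses, and derives niche-sharing set memberships and core
    microbiota at detection/prevalence thresholds. A Dirichlet-multinomial
    simulator with exported ground truth generates data with the hierarchical
    structure the models assume.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    lme4,
    biomformat,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
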