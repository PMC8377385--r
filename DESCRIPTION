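Package: edgekin
Title: Kinase-Substrate Edge Biomarkers for Two-Class Prognostic Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Constructs per-sample kinase-substrate edge features from gene
    expression by class-conditional standardization (the within-class mean of
    an edge feature equals the within-class Pearson correlation of the pair),
    selects differential node and edge features between two patient classes
    with a Student's t prefilter and L1-penalized logistic regression under
    cross-validated penalty choice, and evaluates prognostic value by
    repeated random-split random survival forest concordance, Cox
    proportional-hazards models, and median-split Kaplan-Meier
    stratification. Includes a seeded synthetic two-class survival-cohort
    generator with planted differential means, planted class-specific
    kinase-substrate correlations, and Weibull proportional-hazards event
    times, plus hypergeometric gene-set over-representation analysis and a
    reproducible staged pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    ranger,
    stats,
    survival,
    tools,
    utils,
    withr,
    yaml
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
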