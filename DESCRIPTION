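Package: coxprior
Title: Literature-Informed Priors and Bayes Factors for Cox Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Elicits zero-centered Normal priors for the log hazard ratio in
    Cox proportional hazards regression from corpora of published hazard
    ratios and confidence intervals. Provides text-mining utilities that
    extract the first complete hazard-ratio plus confidence-interval tuple
    from abstracts, validity screening of the extracted tuples, pooled-sample
    aggregation of study-level effects into a Normal prior per biomedical
    subfield, a quadrature-based Bayes factor for one-predictor Cox
    regression under Normal or truncated-Normal priors, sequential evidence
    monitoring with stopping thresholds, and seeded generators for synthetic
    abstracts, effect corpora, and two-arm survival data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite,
    optparse,
    withr
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Config/testthat/edition: 3
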