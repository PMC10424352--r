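Package: eyegee
Title: Gene-Diet Interaction Analysis for Paired-Eye Case-Control Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying gene-environment interaction in ophthalmic
    case-control studies that analyse the individual eye as the unit of
    observation. Computes a nine-component Mediterranean-diet adherence score
    (mediSCORE) from food-frequency questionnaire data, a weighted 52-variant
    genetic risk score from genotypes, and Rotterdam-stage case/control
    classification; fits eye-level logistic regression by generalized
    estimating equations with an exchangeable working correlation and robust
    (sandwich) covariance; and reports multiplicative and additive interaction
    measures (RERI, AP, SI) with delta-method and cluster-bootstrap confidence
    intervals in the Knol-VanderWeele layout. A synthetic-cohort generator
    with a marginally-specified correlated-outcome model supports testing and
    power exploration without access to individual-level study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr, vcfR, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
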