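Package: mstnmf
Title: Microbial Source Tracking via Reference-Anchored Non-Negative
    Matrix Factorization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the proportion of each candidate microbial source
    (plus one aggregate unknown source) in a target microbiome sample.
    The taxa-abundance vector of the sink is factorized as a convex
    mixture of latent source profiles that are anchored to the observed
    reference profiles, and the constrained factorization is solved with
    an alternating direction method of multipliers (ADMM) whose simplex
    constraints are enforced by exact water-filling projections.
    Includes Jensen-Shannon divergence and Pearson correlation
    evaluation metrics, and a synthetic benchmark generator emulating
    sparse environmental source profiles with controllable inter-source
    divergence, Pareto mixing proportions, designated unknown and
    irrelevant sources, and multinomial observation noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr, knitr, rmarkdown
Config/testthat/edition: 3
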