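Package: diabproj
Title: Dynamic Multistate Projection of Diabetes Burden
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Projects the future burden of diabetes in an adult population
    with a Bayesian logistic growth model for diagnosed-diabetes incidence
    (AR(1)/MA(1)/ARMA(1,1) error structures, scenario extraction from the
    posterior) feeding three-, four-, and five-state annual
    difference-equation compartment models (no diabetes, undiagnosed,
    diagnosed; high/low-risk split of the nondiabetic pool; preventive
    intervention overlay). Compartment totals are kept exactly consistent
    with an external demographic projection by back-calculating the
    nondiabetic death rate and allocating births and net migration across
    states. Includes a synthetic-data module emulating census-style
    demographic projections and surveillance incidence series so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    coda,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    rjags,
    optparse
Config/testthat/edition: 3
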