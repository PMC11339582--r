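Package: crisisim
Title: Discrete-Event Simulation of Text-Based Crisis Counseling Operations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A discrete-event simulation toolkit for 24/7 text-based crisis
    counseling services. Estimates staffing needs, queue performance and
    service-pledge conformity by combining stochastic arrival generation
    (nonhomogeneous Poisson by Lewis-Shedler thinning, and self-exciting
    Hawkes re-contacts), censored-survival estimation of caller patience,
    scaled-beta service-duration models, an unobserved-components state-space
    demand forecaster with bias-adjusted Box-Cox back-transformation, and
    cost-effectiveness staffing analysis. Includes a synthetic event-log
    generator with known ground truth so every estimator and the simulator
    are testable without access to any real service database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
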