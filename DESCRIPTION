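Package: cascadecea
Title: Cost-Effectiveness of BRCA1/2 Cascade Testing and Risk-Reducing
    Surgery for Relatives of Ovarian-Cancer Patients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Markov cohort state-transition model for the cost-effectiveness
    of germline BRCA1/2 cascade genetic testing plus risk-reducing surgery
    (bilateral prophylactic mastectomy and salpingo-oophorectomy) offered to
    first-degree female relatives of ovarian-cancer patients, compared with
    usual care, from the perspective of the Brazilian National Health System
    (costs in 2014 BRL). Provides a validated parameter set with sensitivity
    ranges, constant-hazard conversion between cumulative penetrance and
    annual transition probabilities, an annual-cycle cohort engine with 5%
    discounting of costs and cancer cases, incremental cost-effectiveness
    (ICER) computation with dominance and threshold classification, one-way
    deterministic sensitivity analysis (tornado diagram), and an
    individual-level Monte-Carlo microsimulation that serves as an
    independent oracle for the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
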