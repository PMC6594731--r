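Package: ageplacecost
Title: Population-Wide Cost Estimation for Assistive Technologies Enabling Ageing in Place
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a five-stage framework for estimating the population-wide
    cost of digital assistive technologies that help older people remain in their
    own homes: progressive (cohort-survival) forecasting of the 65+ population
    with trended death rates and net migration, assistance-need estimation,
    combinatorial allocation of the assisted population across chronic-disease
    comorbidity strata for eight common chronic diseases, a life-cycle technology
    cost engine with low/average price scenarios, and a seeded synthetic-data
    generator for every input the pipeline consumes. Ships the published regional
    demographic and comorbidity tables for an Australian case study region as
    plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
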