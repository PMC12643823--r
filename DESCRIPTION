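Package: grassipm
Title: Integrated Population Modelling and Climate Projection for a
    Declining Grassland Songbird
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits a Bayesian two-sex, three-stage integrated population
    model (IPM) joining annual counts, capture-recapture histories, and
    productivity data for a grassland songbird population; computes
    stochastic population growth and numerical perturbation sensitivities
    and elasticities of the growth rate to each vital rate; estimates
    direct and net effects of breeding-season weather (wet-bulb
    temperature, storms, lagged ESPI) on vital rates and growth via a
    posterior-propagating path analysis; and projects population size to
    2100 from downscaled per-GCM precipitation. Includes a synthetic-data
    generator so the whole pipeline is testable end to end without field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
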