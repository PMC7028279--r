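Package: pharmsim
Title: Multiagent Simulation of Trust and Disruptions in Pharmaceutical
    Supply Chains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time multiagent simulator for a three-echelon
    pharmaceutical supply chain (manufacturers, distributors,
    healthcenters). Agents follow base-stock ordering with proportional or
    preferential rationing; healthcenters may split orders across
    distributors in proportion to an exponentially smoothed on-time
    delivery rate (attributed trustworthiness); one distributor can plan
    with a finite-horizon Theory-of-Mind model of the other agents.
    Includes capacity-reduction disruption profiles, a scenario engine
    with warm-up detection and cost-change accounting, sensitivity sweeps
    over the trust smoothing factor, tidy trace output, and ggplot2
    visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
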