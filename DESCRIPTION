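Package: swarmevol
Title: Evolution of Pheromone Recruitment and Traffic Rules in Foraging Robot Swarms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An embodied agent-based simulator of ant-like robot swarms that
    forage between a nest and a food source using trail pheromones, with
    genotype-controlled collision reactions (Stay/Leave) at four binary loci.
    On top of the foraging layer the package provides Wright-Fisher evolution
    of clonal swarms with per-locus mutation, genealogy tracing and
    mutation-order classification, and the analytical stochastic-tunneling
    model (fixation probabilities, tunneling rate, expected time to fixation)
    used to study why the neutral traffic-rule locus tends to mutate before
    the pheromone-responsiveness locus on the path to the high-fitness
    genotype.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
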