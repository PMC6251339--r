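Package: evocage
Title: Evolutionary Discovery of Shape-Persistent Porous Organic Cages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An evolutionary algorithm for the design of two-component imine
    porous organic cages. Tri-topic aldehyde and di-topic amine building blocks
    are assembled on polyhedral topology graphs (Tri4Di6 tetrahedron, Tri8Di12
    cube), relaxed with a pluggable optimizer, and scored with a scalarized
    fitness combining cavity diameter, window diameter and window asymmetry
    penalties. Populations evolve by selection (fittest, roulette wheel with or
    without elitism, stochastic universal sampling), single-gene crossover and
    random or Dice-similarity mutation over Morgan fingerprints. Includes a
    precomputed-landscape benchmarking protocol for measuring the probability
    of rediscovering a known global optimum against an analytic random-search
    baseline, plus synthetic building-block libraries, toy cage geometries with
    closed-form properties, and synthetic fitness landscapes for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
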