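Package: geminicoev
Title: Gene-Culture Coevolutionary Models of Human Twinning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Formal models for the evolutionary dynamics of dizygotic twinning
    in humans. Implements a resource-dependent ovulation-strategy fitness model
    with its quadratic selection condition and the partition of resource space
    into adaptive regions; a cumulative twin-maternity prevalence formula for
    different fertility regimes; and a gene-culture coevolution model in which
    a geminophilous redistribution pool buffers the cost of twin births,
    including the analytic invasion condition for a high-twinning mutant, a
    conservative contribution-rate bound, and a full stochastic Wright-Fisher
    simulation of the four culture-by-genotype types. Scenario configurations
    are declarative (YAML), every stochastic operation is seeded, and a thin
    command-line interface is provided for running scenarios from a shell.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
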