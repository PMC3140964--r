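Package: fluxpattern
Title: Elementary Flux Patterns, Pathway Discovery and Pathway Energetics in
    Stoichiometric Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constraint-based analysis of stoichiometric metabolic
    networks at steady state. Implements exhaustive enumeration of elementary
    flux modes for small networks (nullspace double-description with exact
    rational arithmetic), enumeration of elementary flux patterns over a
    designated subsystem of a larger network via cardinality-ordered
    optimization, an iterative pathway-discovery procedure built on flux
    patterns and essential-reaction detection, K-shortest elementary flux mode
    enumeration with cofactor externalization, and an energetics layer that
    computes net ATP costs of routes under cofactor-balancing policies, Gibbs
    free energy changes of overall conversions, and gluconeogenic energy /
    glucose storage efficiencies. Ships programmatic fixtures for classic
    example networks (glycolysis plus pentose phosphate pathway, TCA cycle
    with and without the glyoxylate shunt, ketogenesis and acetone
    degradation) together with SBML and TSV input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
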