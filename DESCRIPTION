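Package: fluxlattice
Title: Lattice-Based Flux Coupling Analysis with Double and Multiple Knockouts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Qualitative analysis of genome-scale metabolic network models
    through the lattice of reaction supports of the steady-state flux cone.
    Computes blocked reactions, directional and partial flux couplings and
    partial-coupling equivalence classes, and extends flux coupling analysis
    to double and multiple reaction knockouts (joint couplings) and to single
    and double gene knockouts via gene-protein-reaction rules.  Includes a
    linear-programming feasibility oracle with witness-pathway reuse, an
    exact brute-force reference implementation for small networks, readers
    for SBML Level 3 (FBC) and a JSON model dialect, and summary statistics
    of knockout impact, knockout options and biomass-blocking knockouts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    pracma,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
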