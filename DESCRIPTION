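Package: fluxspace
Title: Exact Characterization of the Optimal Solution Space of Flux Balance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Enumerates and characterizes the space of alternative optima of
    flux balance analysis (FBA) problems in exact rational arithmetic. The
    optimal solution space of a constraint-based metabolic model is a
    polyhedron; fluxspace decomposes it into a Minkowski sum of vertices,
    extreme rays, and linealities, detects flux modules (subnetworks with
    fixed net input-output stoichiometry over the optimum), enumerates
    vertices per module so that whole-network vertex counts are obtained as
    products of small per-module counts, enumerates elementary flux modes
    (EFMs) of small networks and relates them to vertices, and collapses the
    optimum with secondary objectives: pathway length (a mixed-integer
    program), sum of absolute fluxes, and protein cost derived from
    gene-protein-reaction rules. All core computations (simplex, flux
    variability analysis, double description, rank tests) run over exact
    rationals so that counts and verdicts are tolerance-free.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
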