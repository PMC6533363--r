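Package: aurox
Title: Gold Oxidation Geochemistry and Auriferous-Soil Microbiome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying microbially mediated gold oxidation under Earth
    surface conditions. Provides an equilibrium thermodynamics engine (Hess-law
    reaction combination, Gibbs energy, equilibrium constant and electrode
    potential conversions, Nernst pH-Eh boundary lines), two-stage pH-Eh
    predominance (Pourbaix) diagrams for gold in carbonate- and sulfur-bearing
    systems with solubility contours, colorimetric Au(III) microcosm kinetics
    (standard-curve calibration, phase-wise oxidation rates, Au(III)-pH
    correlation), alpha-diversity and gold-hotspot statistics for site-by-OTU
    tables, co-occurrence network construction with greedy modularity and
    stress centrality, and seeded synthetic-data generators that emulate the
    microcosm and two-area field designs for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ggplot2
Config/testthat/edition: 3
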