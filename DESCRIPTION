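Package: cdftpept
Title: Conceptual-DFT Computational Peptidology Descriptors and Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for conceptual density functional theory
    (CDFT) studies of peptide natural products. Computes the global reactivity
    descriptor set (electronegativity, hardness, softness, electrophilicity,
    nucleophilicity, electrodonating and electroaccepting powers, net
    electrophilicity) from frontier orbital energies, validates density
    functionals against the ionization energy theorem via Koopmans-deviation
    (KID) indices and a global KID descriptor, computes grid-based Fukui
    functions and the dual descriptor from Gaussian cube density files,
    applies a hardness-based pKa QSAR, and assembles bioactivity and ADMET
    classification reports. Ships the published energetics of the marine
    cyclohexadepsipeptides Veraguamides A-G as worked fixtures and a
    synthetic-data generator with known ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
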