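Package: dosewedge
Title: Dose-Resolved Radiation-Damage Analysis for Room-Temperature Serial Crystallography
Version: 0.1.0
Authors@R: person("Dosewedge", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates and analyses dose-resolved serial-crystallography
    experiments on multiple small protein crystals. Provides Miller-index
    symmetry machinery for cubic point group 23, a Wilson-statistics
    intensity simulator with per-crystal exponential dose decay and a
    two-state indexing ambiguity, correlation-based resolution of that
    ambiguity, relative K/B scaling of dose wedges, exponential decay
    fitting with derived damage metrics (specific dose, half dose,
    undamaged fraction), and standard merging statistics (R_merge, R_meas,
    CC1/2, CC*, completeness, multiplicity).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
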