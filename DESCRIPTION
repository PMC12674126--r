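Package: actinconf
Title: Conformational Metrics for Actin Subunits and Filament Nuclei
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the twisted-to-flattened (G-to-F) conformational
    transition of actin subunits from crystallographic and trajectory
    coordinates. Computes the subdomain center-of-mass flattening dihedral
    (phi SD1-SD4), SD1/SD2 center-of-mass offsets against G- and F-actin
    references after SD3/SD4 superposition, W-loop gate distances
    (Tyr143-Gly168/Tyr169) and open/closed calls, matched-Calpha Kabsch
    superposition RMSDs, Shrake-Rupley solvent-accessible surface and
    pairwise interface buried areas, nucleus tilt/displacement measurements,
    and gate open-fraction statistics over multi-model trajectories. Includes
    a synthetic actin-like conformer generator with controllable flattening
    dihedral, gate geometry and two-state gate dynamics so the full analysis
    chain is testable without external coordinate downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
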