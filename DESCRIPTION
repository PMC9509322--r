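Package: bellevans
Title: Ligand Residence Times from Steered-MD Pull Forces via the Bell-Evans Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Post-processing of steered molecular dynamics (SMD) constant-velocity
    pulling experiments for absolute ligand residence-time prediction. Reads
    GROMACS-style pull-force and pull-distance time series, extracts per-replica
    rupture events, computes ensemble statistics with bootstrap replica-sufficiency
    analysis, fits mean rupture force against the natural logarithm of the loading
    rate, and converts the fit into a dissociation rate constant and residence time
    under the Bell-Evans model. Also aggregates MMPBSA binding-energy components,
    determines binding-pocket residues from PDB coordinates, and classifies
    hotspot and anti-hotspot residues across two ligand systems. A stochastic
    rupture simulator generates realistic pull-force traces under a Bell escape
    rate so the entire pipeline can be exercised and validated without an MD
    engine.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    bio3d,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
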