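Package: atpsense
Title: Hydrogen-Bond, Contact and Free-Energy Analysis of ATP-Sensor
    Protein Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for structural ensembles of the bacterial
    F1Fo-ATP-synthase epsilon subunit and related ATP-sensor proteins.
    Detects hydrogen bonds by geometric criteria and scores them with a
    distance-based empirical energy, counts repulsive electrostatic
    contacts among basic binding-site residues and the Mg2+ ion,
    classifies the Mg2+-ATP coordination state, computes helix
    centre-of-mass and superposition metrics, integrates
    thermodynamic-integration window tables, scans multiple sequence
    alignments for binding-site substitutions, and aggregates per-variant
    statistics into a comparative binding-affinity ranking.  Ships a
    synthetic-ensemble generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    graphics,
    jsonlite,
    pracma,
    seqinr,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
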