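Package: cyclostretch
Title: Quantifying Cell Reorientation Under Uniaxial Cyclic Substrate Stretching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how adherent epithelial cells reorient
    perpendicular to the direction of uniaxial cyclic stretching. Implements
    difference-imaging quantification of protrusion and retraction with a
    diagonal quadrant partition at the cell centroid, moment-ellipse
    morphometrics (orientation index cos 2-theta, axial/transverse rectangle
    lengths, spreading area), fiducial-grid strain measurement on
    micropatterned elastic substrates, and a synthetic-data module that
    simulates per-cycle retraction/protrusion shape dynamics of single cells
    under programmable stretch waveforms, with drug-condition presets and
    full ground-truth logging. An experiment pipeline orchestrates
    simulate-measure-tabulate runs and writes CSV/TIFF/JSON outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
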