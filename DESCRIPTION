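Package: antennascan
Title: Kinematic and Plume-Interaction Analysis of Active Antennal Smelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for active olfactory sensing in tethered
    insects. Converts 3D-tracked head, antennal-tip and tarsus coordinates
    into antennal azimuth/elevation angles, heading, angular speeds and
    normalized (head-centred, antenna-length-scaled) coordinates; computes
    spatial occupancy maps, kernel density curves, distance to an odour
    stream, antennal sweeping ranges, event-triggered baseline changes with
    sham correction and responsive-antenna labelling; detects steps and leg
    speed correlations; quantifies spectral content with FFT summary spectra
    and a continuous Morlet wavelet band-power statistic scaled to the
    pre-stimulus baseline; analyses smoke-visualisation image sequences
    (threshold, mask, row-wise pixel profiles) and photo-ionisation detector
    traces (extrema detection, fluctuation rate and magnitude, regression on
    antennal speed); and computes shelter preference indices for arena
    assays. A synthetic-data generator with machine-readable ground truth
    emulates every input for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'config.R'
    'io.R'
    'kinematics.R'
    'spatial.R'
    'stepping.R'
    'spectral.R'
    'plume.R'
    'valence.R'
    'synthetic.R'
    'pipeline.R'
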