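Package: tensionfret
Title: FRET Tension-Sensor Analysis for Desmosomal Puncta
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies molecular tension across junctional proteins from
    genetically encoded FRET tension sensors. Provides Poisson
    maximum-likelihood lifetime fitting of TCSPC-FLIM photon histograms and
    FRET efficiencies from donor lifetime shortening; sensitized-emission
    ratiometric FRET indices from three-channel acquisitions with flat-field
    correction, rolling-ball background removal and linear spectral
    de-mixing; punctum segmentation and bipartite-matching particle tracking
    of micropipette-pull recoil experiments with recoil distance and angle
    geometry; image-grouped mixed-model statistics for sensor-vs-control
    FRET differences; and a synthetic-scene generator producing
    ground-truth-labelled inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
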