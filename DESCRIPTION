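Package: wtpet
Title: Flat-Panel Total-Body PET Simulation and NEMA NU-2 Performance
    Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale Monte Carlo simulation and performance evaluation of
    a walk-through total-body PET scanner built from two flat panels of
    monolithic, depth-of-interaction capable BGO detectors, compared against
    a cylindrical total-body scanner with pixelated LSO crystals. Provides
    scene construction for the NEMA NU-2 phantoms (point sources, sleeved
    line sources, scatter cylinder, image-quality body), 511 keV photon
    transport with Klein-Nishina Compton sampling, detector response models
    for monolithic and pixelated readout, coincidence sorting with
    ground-truth event classification, time-of-flight list-mode MLEM
    reconstruction with sensitivity and attenuation correction, and the
    NEMA NU-2 metric suite (spatial resolution, sensitivity, count rates,
    NECR, scatter fraction via single-slice rebinning, contrast recovery).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    data.table,
    yaml,
    jsonlite,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
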