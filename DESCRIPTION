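Package: voxres
Title: Voxel-Wise Local Resolution Estimation for CryoEM Density Maps by 3D Convolutional Regression
Version: 0.1.0
Authors@R: person("voxres", "maintainers", email = "voxres@example.org", role = c("aut", "cre"))
Description: Estimates a per-voxel "local resolution" quality measure for 3D
    cryo-electron microscopy density maps. A small 3D convolutional neural
    network is trained to recognise the texture of density maps low-pass
    filtered at known cutoffs (a raised-cosine filter bank applied to maps
    simulated from atomic or pseudo-atomic models); at inference time the map
    is scanned with a 13x13x13 sliding window and the regressed cutoff is
    assigned to the centre voxel. Unlike signal-to-noise-ratio based local
    resolution estimators, the texture-based estimate responds to B-factor
    sharpening, which also yields a simple oversharpening audit: sweep global
    B factors and compare a low percentile of the estimated resolution
    distribution against an SNR-based reference. Includes MRC2014 volume and
    PDB model input/output, Fourier-space filtering, sharpening, phase
    randomization and resampling, a synthetic polymer-structure generator so
    the full train/predict cycle runs without downloads, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
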