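Package: polarcomp
Title: Competition Between Polarity Clusters in a Stochastic
    Reaction-Diffusion Model of Yeast Cdc42 Polarization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a stochastic membrane-cytosol reaction-diffusion
    model of Cdc42/Bem1-GEF polarity establishment in budding yeast on a
    periodic (torus) membrane with a well-mixed cytoplasm, and implements
    the analyses with which winner-take-all competition between polarity
    peaks is established: peak detection, waistline and flux accounting,
    rate-balance curves, two-peak competition experiments, dwell-time
    (quasi-steady-state) half-time analyses, linear stability analysis on
    the torus and on a sphere with cytosolic diffusion, and
    fluorescence-microscopy quantification (spot segmentation, tracking,
    vicinity intensity traces, coexistence times, FRAP/FLIP curve
    analysis) exercised on synthetic movies and traces with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    minpack.lm,
    stats,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
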