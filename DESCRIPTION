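Package: trastkit
Title: Dark-State Fluorescence Bar-Coding by TRAST and FCS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and fitting of photoinduced dark-state kinetics of
    fluorophores (cyanine trans-cis photoisomerization and rhodamine triplet
    crossing) in four readout modalities: stationary transient-state (TRAST)
    pulse-train curves, fluorescence correlation spectroscopy (FCS)
    autocorrelation curves, microfluidic flow-TRAST fluorescence profiles,
    and pixel-wise TRAST images. Includes brightness-weighted mixture models
    and probability-density based unmixing of spectrally identical
    fluorophore mixtures, plus a synthetic-data generator with known ground
    truth for all four modalities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite,
    yaml,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
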