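Package: rcfilm
Title: Absorbed-Dose Energy Response of Radiochromic Films Around
    Brachytherapy Sources
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the relative absorbed-dose energy response correction R
    of radiochromic film emulsions (EBT, EBT2, RTQA, XRT, XRQA, HS) along the
    transverse axis of high-energy brachytherapy sources (Co-60, Cs-137,
    Ir-192, Yb-169) in water and solid phantoms.  Provides elemental photon
    interaction and mass energy-absorption coefficient tables with log-log
    interpolation, mixture-rule material physics (mu/rho, mu_en/rho, effective
    atomic number, mean Z/A), discrete source spectra, an analog photon Monte
    Carlo transport engine for cylindrical phantoms with track-length fluence
    tallies in thin shells, fluence-to-collision-kerma conversion, and the
    response analyses built on them (R versus distance, analytic R versus
    energy, fluence-weighted mean energies, phantom-material ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
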