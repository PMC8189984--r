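Package: ftirhdx
Title: Protein Secondary Structure from FTIR Spectra with Hydrogen/Deuterium Exchange
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies protein secondary structure (alpha-helix, beta-sheet
    and irregular "Others" content) from Fourier-transform infrared spectra
    recorded at several hydrogen/deuterium-exchange timepoints. Provides the
    amide I/II preprocessing chain (straight-line baseline correction, vector
    normalization, sub-gridpoint peak localization, timepoint concatenation),
    DSSP-derived reference structure fractions with ordered/disordered helix
    and parallel/antiparallel sheet splits, amino-acid side-chain spectral
    correction, three calibration engines (NIPALS partial least squares with
    interval scanning, least-squares support vector machine regression, and
    ascending stepwise linear regression), leave-one-out and Kennard-Stone
    validation with RMSE and zeta efficiency metrics, and a synthetic spectra
    generator emulating class-dependent exchange kinetics for end-to-end
    testing without measured spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
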