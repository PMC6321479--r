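Package: idpbiophys
Title: Biophysical Characterization of Intrinsically Disordered,
    Self-Associating Protein Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimators and synthetic-data generators for the standard
    solution-biophysics toolbox used to decide whether a protein domain is
    intrinsically disordered and whether it self-associates: sequence-based
    hydrodynamic radius predictors (equivalent-sphere, folded and unfolded
    scaling laws), Stejskal-Tanner fitting of pulse-field-gradient NMR
    diffusion decays with internal-reference conversion to a Stokes radius,
    Stern-Volmer quenching analysis and its protein-concentration trend,
    intensity-weighted spectral summaries and two-state chemical/thermal
    denaturation fits with physicality diagnostics, far-UV CD deconvolution
    against a packaged basis, Guinier and generalized-Gaussian-coil analysis
    of small-angle scattering curves with Flory-exponent classification,
    size-exclusion chromatography calibration with oligomer-order assignment,
    and a dilution-ITC dimer-dissociation model with an adequacy test.
    Every modality ships a seeded generator so the full pipeline is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    pracma,
    jsonlite,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
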