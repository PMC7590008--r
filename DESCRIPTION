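Package: fibrildis
Title: Dissolution Kinetics of Peptide Fibrils from Isothermal Titration
    Calorimetry Dilution Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate, preprocess and decompose isothermal titration
    calorimetry (ITC) differential-power traces from dilution-quench experiments
    on self-assembled peptide fibrils. Each injection is modelled as the sum of
    fast dilution peaks (half-sine and Lorentzian shapes) and a slow exothermic
    dissolution signal with a sigmoidal lag phase; nonlinear least-squares
    fitting extracts per-injection dissolution enthalpies, rate constants and
    lag exponents. Includes a synthetic-experiment generator with known ground
    truth, derivative-threshold peak detection with two-regime polynomial
    baseline correction, and downstream models: a reversible
    attachment/detachment rate law versus concentration, the diffusion-limited
    dissolution time of a spherical aggregate, and a partial-deprotonation pH
    model above the monomer solubility.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
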