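Package: enzchar
Title: Enzyme Kinetics, Thermodynamics and Expression-Optimization Characterization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete quantitative characterization workflow for
    glycoside hydrolases and similar enzymes, built around the CelC307
    endoglucanase case study: reducing-sugar assay calibration and
    activity units, Michaelis-Menten nonlinear fitting with catalytic
    constants, Lineweaver-Burk based inhibition-mode classification,
    Arrhenius/Eyring activation thermodynamics, first-order irreversible
    thermal-inactivation kinetics (half-life, decimal reduction time and
    the associated state functions), Plackett-Burman screening and
    central-composite response-surface optimization with a full blocked
    ANOVA, and ProtParam-style protein physicochemical indices. A seeded
    synthetic-data generator emulates every input the pipeline consumes,
    and a consistency checker cross-validates published parameter tables
    against their own printed inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    seqinr,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
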