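Package: tagfold
Title: Thermodynamic Lability of Proteasome-Targeting Tags and Their Substrates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of how thermodynamically labile
    ubiquitin-like proteasome-targeting tags (such as Fat10) destabilize
    their substrates. Implements two-state equilibrium unfolding fits
    (chemical and thermal denaturation), native-state proteolysis
    energetics (k_obs, K_op and the proteolysis free energy), amide
    proton temperature-coefficient regression with segment-level
    comparison, Lipari-Szabo model-free analysis of 15N relaxation with
    an entropy-meter conversion of order parameters to conformational
    entropy, and molecular-dynamics plasticity metrics (native-contact
    fraction, beta-sheet hydrogen-bond fraction, RMSF/RMSD, radii of
    gyration, Boltzmann-inverted free-energy landscapes, principal
    component analysis and contact-disruption maps). A synthetic-data
    module generates every input modality from known ground-truth
    parameters so that each pipeline stage is testable by parameter
    recovery.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    bio3d,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
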