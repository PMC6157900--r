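Package: pulsewave
Title: Patient-Specific Arterial Pulse Wave Propagation Modelling and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and inverse identification of a one-dimensional
    haemodynamic model of the 55 larger systemic arteries. Blood flow in a
    bifurcating binary tree of tapering elastic vessels is solved with a
    two-step Lax-Wendroff scheme coupled to three-element Windkessel outflow
    models, and six patient-specific parameters (small- and large-artery
    stiffness, cardiac output, heart ejection peak time, and terminal
    resistance and compliance scalings) are estimated from a single calibrated
    radial pressure waveform by particle swarm optimisation with local
    refinement. The package also provides pulse wave analysis indices
    (augmentation index, sub-endocardial viability ratio, ejection duration),
    model-predicted pulse wave velocity, an arteriovenous fistula extension
    with radial-to-aortic transfer function analysis, a virtual-cohort
    generator emulating a haemodialysis study design, and the matching
    statistical battery (propensity score matching, Friedman-type rank tests
    for unbalanced repeated measures, Scheffe-adjusted pairwise contrasts,
    Spearman correlation clustering).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    signal,
    minpack.lm,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
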