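Package: ocupkpd
Title: Two-Compartment Ocular Pharmacokinetics and Pharmacodynamics of
    Intravitreal Anti-VEGF Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and Bayesian analysis of a two-compartment
    (vitreous / aqueous humor) binding-kinetics model of ocular VEGF
    suppression following a single intravitreal bolus of an anti-VEGF
    antibody such as ranibizumab. Provides a stiff ODE implementation of
    the mass-action system with compiled derivatives, synthetic data
    generation with additive observation noise and ELISA
    limit-of-quantification censoring, the standard below-LLQ substitution
    corrections, differential-evolution MCMC with truncated-normal priors
    and rank-normalized split R-hat diagnostics, extended Fourier amplitude
    sensitivity testing (eFAST), profile likelihood for ELISA contamination
    fractions, and experiment drivers for data-correction and
    sampling-schedule studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
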