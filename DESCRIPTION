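Package: acetokin
Title: Threshold Kinetic Models for Hydrogen-Limited Growth of Reductive
    Acetogens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Batch-culture growth and metabolism models for reductive
    acetogens such as Blautia hydrogenotrophica: Monod and first-order
    hydrogen-uptake kinetics, three hydrogen-threshold formulations (hard
    cutoff, sigmoid-gated uptake after Ribes et al., and reversible
    Michaelis-Menten kinetics), and a two-substrate yeast-extract
    extension.  Provides stiff ODE simulation with compiled derivatives,
    Bayesian calibration by adaptive random-walk Metropolis MCMC with
    credible intervals, split-Rhat convergence diagnostics and parameter
    correlations, a synthetic batch time-course generator for
    parameter-recovery studies, and closed-form analyses of
    Wood-Ljungdahl stoichiometry, reversible-kinetics steady states and
    culture unit conversions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
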