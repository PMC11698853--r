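Package: ihp
Title: Intelligent Hitchhiking Particles in Active Brownian Baths
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of a motorless agent (an intelligent
    hitchhiking particle, IHP) that achieves persistent directed motion by
    selectively attaching to active Brownian bath particles. Provides the
    periodic two-dimensional bath of (chiral) active Brownian particles
    integrated by a forward Euler-Maruyama scheme, a tabular Q-learning
    trainer producing per-orientation GO/NO-GO decision diagrams, a
    continuously forced potential-based variant of the agent, ensemble
    mean-squared-displacement analysis, and the analytic partner-probability
    and drift theory that explains the agent's transport regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
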