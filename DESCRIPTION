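Package: stochallee
Title: Stochastic Difference-Equation Models of Allee Effects and Extinction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of single-species stochastic difference
    equations X[t+1] = f(X[t], xi[t]) X[t] driven by independent and
    identically distributed environmental noise. Provides a catalogue of
    fitness functions with positive and negative density dependence
    (Ricker, Beverton-Holt, mate limitation, predator saturation and their
    combinations), geometric-mean-fitness persistence criteria, regime
    classification (stochastic persistence, conditional persistence,
    unconditional extinction, unbounded growth), deterministic-skeleton
    analysis (smallest positive fixed point, critical point, positive
    attractor versus essential extinction), small-noise invariant-interval
    certification, and seeded Monte-Carlo ensemble experiments including
    persistence-probability curves and asymptotic-dynamics scatter tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    parallel,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
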