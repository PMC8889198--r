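Package: ifdsim
Title: Individual-Based Simulation of the Ideal Free Distribution with
    Personality-Dependent Movement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates foraging consumers distributing themselves over
    resource patches by sequential best-response movement, where stable
    individual differences in 'activity' set how often each consumer
    assesses whether its current patch is suboptimal. Provides consistent
    ratio-dependent type I and type II functional responses, a
    discrete-time scheduler with either a movement-quiescence stopping
    rule or an exact ideal-free-distribution (IFD) stopping rule, an
    equivalent continuous-time event-based (Gillespie) scheduler,
    deviation-from-IFD metrics (intake-rate variance across patches,
    log-log matching slope, brute-force equilibrium enumeration), and a
    reproducible sweep harness with tidy CSV output and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
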