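Package: emergence
Title: Information-Theoretic Detection of Causal Emergence in
    Multivariate Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies causal emergence, downward causation and causal
    decoupling in multivariate dynamical systems.  Provides exact partial
    information decomposition (PID) and integrated information
    decomposition (PhiID) under a minimum-mutual-information redundancy
    for small discrete systems, together with the scalable whole-minus-sum
    criteria Psi, Delta and Gamma applicable to arbitrary discrete or
    continuous time series, with surrogate-based significance testing.
    Ships three self-contained testbeds: parity-preserving Markov toy
    systems, a Game of Life particle collider, and a Reynolds boids
    flocking simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
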