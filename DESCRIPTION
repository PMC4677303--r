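Package: agdyn
Title: Stochastic Evolutionary Dynamics of the Anticipation Game
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finite-population stochastic evolutionary dynamics for the
    Anticipation Game, a Dictator Game preceded by a reputation-based partner
    acceptance phase. Implements pairwise-comparison (Fermi) imitation dynamics,
    fixation probabilities, the small-mutation embedded Markov chain over
    homogeneous bipartite states and its stationary distribution; the
    acceptance-probability curve A(p) and a delta-weighted anticipatory dictator
    fitness solved self-consistently; selection-intensity calibration against
    experimental donation averages; a forward Monte Carlo simulator with explicit
    mutation; and a synthetic-session generator emulating the behavioural
    protocol (30 rounds, 3-round reputation history, random matching).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
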