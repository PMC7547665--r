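Package: friendlyrival
Title: Friendly Rival Strategies in the Iterated Prisoner's Dilemma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Axiomatic analysis of deterministic memory-m strategies for the
    repeated prisoner's dilemma under rare implementation error. Decides the
    three criteria -- efficiency, defensibility and distinguishability --
    exactly, using a negative-cycle test on the adversarial state graph and
    the Freidlin-Wentzell zero-noise limit of the joint play chain;
    exhaustively classifies the memory-one and memory-two strategy spaces;
    provides the CAPRI and TFT-ATFT friendly-rival strategies, recovery-path
    extraction, payoff sampling against random memory-three co-players, and
    a low-mutation Moran simulation with closed-form fixation probabilities
    demonstrating the evolutionary robustness of friendly rivals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
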