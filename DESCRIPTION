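Package: maas
Title: Multiattribute Attention-Switching Sequential Sampling Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts binary choice probabilities, the probability of no
    decision within a finite horizon, and mean choice response times for
    multiattribute choice options under attention switching.  Evidence for
    each attribute accumulates as an Ornstein-Uhlenbeck (or Wiener) process
    approximated by an absorbing birth-death Markov chain; attention moves
    between attributes according to deterministic or random time-and-order
    schedules (Markov order transitions plus discrete attention-time
    distributions).  Includes exact matrix-recursion solvers for
    deterministic and random schedules, a seeded Monte Carlo simulator of
    the discrete chain, and config-driven parameter sweeps over expected
    attention times.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
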