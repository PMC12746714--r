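Package: skillmem
Title: Neural Associative Skill Memories via Temporal Predictive Coding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns repertoires of sensorimotor skill sequences in a single
    two-layer temporal predictive coding network trained with local, Hebbian-like
    updates. The network's energy (sum of squared prediction errors) drives
    out-of-distribution fault detection, per-channel fault isolation, and
    reactive correction, while cued iterative inference expresses the stored
    skill matching an early contextual cue. Includes a seedable kinematic plant
    that generates pick-and-place demonstrations with joint-lock faults and a
    follow-through (context-cued reaching) dataset, backpropagation-through-time
    recurrent baselines, a Z-score associative-skill-memory baseline, and
    metrics (directional compensatory deviation, recall error,
    detection/isolation summaries, speed-accuracy curves).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
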