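Package: branchzones
Title: Branching-Zone Analysis of Apple Shoots with Hidden Semi-Markov Chains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies apple shoots by growth rhythm, duration and period from
    weekly length records; fits constrained left-to-right hidden semi-Markov
    chains to axillary bud-fate sequences; segments shoots into branching zones
    by explicit-duration Viterbi decoding; and compares zone occurrence, zone
    length and lateral-type composition across shoot categories with count GLMs
    and nonparametric tests. A synthetic-data generator with configurable
    ground truth emulates an orchard study so that every pipeline stage and
    parameter-recovery check runs without field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    multcomp,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
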