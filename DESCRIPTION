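Package: moveonset
Title: Mechanisms of Collective Movement Onset: Voting Versus Copying
Version: 0.1.0
Authors@R:
    person("Movement Ecology", "Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to distinguish "voting" from "copying" mechanisms in
    collective departures of animal groups tracked at 1 Hz.  Provides an
    agent-based simulator of group movement onset under copying, all-vote
    and sub-group-vote decision rules; change-point based detection of
    collective departures on group heading and speed; the decision
    parameter (alignment of group mean heading with the departure
    direction) and its cross-correlation with group speed, summarised by
    the max-time-lag and symmetry-index statistics with bootstrap
    confidence intervals; and leader-follower network statistics
    (normalized David's score, triangle transitivity, directional
    consistency) with permutation tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
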