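Package: rcnoise
Title: Resource Competition, Bistability and Noise Propagation in a
    Two-Gene Inhibition Cascade
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Deterministic and stochastic analysis of a synthetic two-gene
    inhibition cascade (GFP represses RFP transcription) under three
    gene-expression resource regimes: unlimited, shared (competing for common
    RNA polymerase and ribosome pools via partition-function rate laws), and
    orthogonal (private pools). Provides exact steady-state enumeration with
    stability, one- and two-parameter saddle-node bifurcation analysis with
    sensitivity reports, an exact Gillespie stochastic simulator (including a
    clamped-mean variant that removes resource-competitive noise), analytical
    noise decomposition via the normalized fluctuation-dissipation theorem,
    and stationary trajectory statistics (CV^2 noise, modality, state
    switching), together with a config-driven experiment runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
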