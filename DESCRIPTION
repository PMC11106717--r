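Package: ntcall
Title: Neuron- and Hemilineage-Level Neurotransmitter Calls from
    Synapse Classifier Predictions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical aggregation of per-synapse neurotransmitter
    classifier outputs for insect EM connectomes. Filters automatically
    detected presynapses, produces neuron-level transmitter calls by
    majority vote with confusion-matrix-weighted confidence scores,
    quantifies within-hemilineage prediction multimodality with base-6
    Shannon entropies, infers the number of transmitters expressed by a
    hemilineage through Bayes-factor model comparison with
    prior-marginalized confusion-matrix smoothing, and measures
    cross-hemisphere and cross-dataset consistency of calls between
    matched homologous neurons. Includes a synthetic study generator that
    emulates the statistical structure of classifier outputs so every
    stage is testable without connectome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    arrow,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
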