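Package: tfap
Title: Transcription Factor Activity Profiling and Regulon Integration
Version: 1.0.0
Authors@R:
    person("TFAP", "Maintainers", email = "tfap@example.org", role = c("aut", "cre"))
Description: Tools for transcription-factor activity profiling (TFAP) from
    reporter/reference constructs quantified by absolute qPCR, and for
    integrating the resulting activity profiles with behavioral phenotyping
    and transcriptome-wide differential expression. Includes promoter-window
    extraction and position-weight-matrix scanning to predict TF regulons,
    regulon-level shift, enrichment and variance statistics, candidate-driver
    ranking, and a fully seeded synthetic-data generator with known ground
    truth so every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
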