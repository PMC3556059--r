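Package: regulab
Title: Workbench for Regulatory Sequence Analysis and Motif Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A scriptable workbench for analysing regulatory genomic sequences
    and predicting transcription factor binding sites and cis-regulatory
    modules. Provides a feature-track data model (DNA, numeric and region
    tracks over genomic sequence sets), condition-driven track operations,
    native position weight matrix and consensus scanning against Markov
    background models, construction and machine-learned generation of
    positional priors, constraint-based module scanning with interaction
    filtering, motif overrepresentation and positional statistics with
    benchmark metrics, a recordable protocol-script language for reproducible
    batch execution, and a generic XML-configured adapter for external
    sequence-analysis programs. A planted-motif synthetic dataset generator
    supports end-to-end evaluation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Biostrings,
    nnet,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
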