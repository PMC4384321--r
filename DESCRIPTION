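Package: smdformat
Title: Single-Molecule Dataset (SMD) Files: Data Model, Content IDs,
    Validation and Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reads, writes, validates and manipulates single-molecule
    dataset (SMD) files, a JSON text format for single-molecule
    time-series data such as smFRET traces. Provides S4 containers for
    traces (index, per-channel values, attributes) and datasets (a fixed
    channel set shared by all traces, declared in a type map), canonical
    serialization with MD5 content identifiers that are stable across
    whitespace, key order and platform, a strict/lenient validator with
    machine-readable issue codes, lossless conversion to and from
    long-format delimited tables, dataset algebra (merge, filter, split,
    derived-channel attachment, summaries), a Markov-chain smFRET trace
    simulator for fully synthetic test data, a conformance corpus, and a
    command-line tool.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    digest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'canonical.R'
    'datamodel.R'
    'validate.R'
    'io.R'
    'convert.R'
    'dataset-ops.R'
    'synth.R'
    'conformance.R'
    'cli.R'
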