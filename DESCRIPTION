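Package: graphsv
Title: Structural Variant Detection on Metagenome Coassembly Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reference-free detection of structural variants (insertions,
    deletions, complex indels and tandem duplications) across a series of
    long-read metagenome samples. A coassembly graph shared by all samples
    is read from GFA 1.0, per-sample read-to-graph alignments are read from
    GAF, and per-node / per-edge log-fold-change of coverage between
    consecutive samples is scanned for SV-specific graph motifs (triangles,
    4-cycles, self-loops and weight >= 2 parallel edges). Includes a seeded
    synthetic fixture generator that implants motifs with controlled
    abundance shifts, writers for SV call tables and Bandage colour
    overlays, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
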