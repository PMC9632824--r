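Package: motifscape
Title: Extraction and Visualization of MEME Motif Discovery Results
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Parses the XML and plain-text result files written by the MEME
    motif discovery program (version 5.x) into a normalized, filterable
    motif-occurrence table with 1-based inclusive coordinates, renders
    motif-location maps (one track per input sequence, one colored box per
    occurrence), optionally row-ordered by and drawn beside a phylogenetic
    tree with tip annotations, and computes position probability matrices
    and information-content sequence logos from the extracted motif site
    sequences. Includes a seeded synthetic-data generator that emits
    MEME-style XML/text files, Newick trees and annotation tables with
    known planted ground truth, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    xml2,
    jsonlite,
    ape,
    ggplot2,
    patchwork
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: MotifDiscovery, SequenceMatching, Visualization, Phylogenetics
RoxygenNote: 7.3.3
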