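Package: duograph
Title: Double-Graph Hybrid Assembly of Accurate and Ultra-Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale implementation of double-graph hybrid genome
    assembly. An accurate-read string graph is built as the backbone,
    ultra-long noisy reads are aligned to its unitigs and encoded as
    integer sequences, a second string graph is assembled in integer
    space, and the resulting integer contigs are incorporated back into
    the backbone to produce the final assembly graph. Ultra-long
    alignments arbitrate graph cleaning via per-edge support weights and
    rescue critical contained reads. Haplotype-resolved assemblies are
    emitted by marker-based graph binning for diploid and polyploid
    samples. Includes a diploid/polyploid genome and read simulator with
    ground truth, GFA/PAF export, and truth-based evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    stringi,
    jsonlite,
    yaml,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
VignetteBuilder: knitr
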