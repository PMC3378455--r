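Package: denovokit
Title: De Novo Transcriptome Assembly, Annotation and Expression Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An integrated toolkit for reference-free transcriptome studies
    built on short paired-end reads: quality filtering of paired reads with
    positional quality profiling and adapter detection, k-mer counting and a
    de Bruijn unitig assembler with k-mer-size sweep selection, greedy
    sequence-identity clustering with terminal-overlap merging and best-hit
    gene grouping, annotation transfer with GO-slim classification and
    hypergeometric term enrichment, mismatch-tolerant read mapping with RPKM
    expression quantification and fold-change classes, microsatellite (SSR)
    and GC-content marker profiling, and a seeded synthetic-data generator
    with planted ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    jsonlite,
    methods,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
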