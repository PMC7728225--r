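Package: epvkit
Title: Annotation and Dual-Host Expression Partitioning of Entomopoxvirus Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for annotating linear double-stranded DNA poxvirus genomes and
    quantifying the replication-versus-virulence split of viral gene expression
    between two insect hosts. Provides deterministic open reading frame calling,
    inverted terminal repeat detection, degenerate early-promoter motif scanning,
    functional gene classification with a poxvirus core-gene census, core-gene
    synteny dot plots with collinear block detection, alignment trimming and
    concatenation for phylogeny preparation, FPKM-based two-group differential
    expression with false discovery rate control and Ward clustering, and a
    negative-binomial count simulator with planted fold changes for end-to-end
    validation against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    jsonlite,
    mclust,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
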