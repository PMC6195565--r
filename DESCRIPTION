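Package: evsmallrna
Title: Small Non-Coding RNA Profiling of Extracellular Vesicle Sequencing Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for small RNA sequencing of extracellular
    vesicle (EV) preparations and their conditioned-media controls. Implements
    a hierarchical read annotation (spike-ins, outmapped nuisance sequences,
    mature miRNAs with isomiR tolerance, genomic small-RNA classes), isomiR
    calling and dominance summaries, counts-per-million detection filtering,
    spike-in normalization with a two-fold media background filter, an exact
    negative-binomial two-group test with tagwise dispersion and
    Benjamini-Hochberg correction, and average-linkage sample clustering.
    Ships a seeded synthetic-data generator emulating a two-group EV study
    design (negative-binomial counts, isomiR read variation, spike-ins, and
    medium-derived background) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    optparse,
    withr
Config/testthat/edition: 3
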