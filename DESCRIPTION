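Package: chromdissect
Title: Chromatin-State Dissection of Transcription-Factor Binding Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies transcription-factor binding sites by differential
    chromatin accessibility between two conditions (pioneer, pre-open,
    bound-but-closed, and closing classes) from ATAC-seq cut-site counts
    using a conditional exact rate test with configurable overdispersion
    and Benjamini-Hochberg FDR control. Provides peak-centered signal
    profiling (metagenes, read-density heatmap matrices, per-locus
    normalized MNase-seq profiles), quantitative scores for nucleosome
    eviction, flanking-array phasing and array sliding, a thermal-stability
    contrast for ChIP signal, and a seeded synthetic-chromatin read
    simulator with planted nucleosome architectures that serves as ground
    truth for the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
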