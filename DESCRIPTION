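Package: exonpatch
Title: Discovery of Exons Hidden in Genome-Assembly Gaps from Assembled
    Transcripts and Genomic Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finds exons hidden inside blocks of unknown sequence ("N-islands")
    in a draft genome assembly by cross-examining de novo assembled transcript
    objects, reference transcript models, and short genomic DNA reads. Splice
    junctions of annotated transcripts are classified as covered, bridged or
    half-bridged by ungapped local alignment of transcript objects; bridging
    inserts are validated by a translated-alignment improvement test against a
    homologous peptide with a scrambled-insert control; genomic reads are
    locally aligned to transcript objects to grow consensus genomic islands
    with intronic tails by iterative majority consensus; and the junctions
    between islands are tested against a donor/acceptor position-weight model
    (information-content score in bits, GT..AG two-step test) to certify
    splice-consistent "connected islands", recover hidden exon sequence with
    exact splice boundaries, and flag chimeric (track-crossing) assemblies.
    Includes a synthetic-data generator emulating a GC-rich multi-exon genome
    with N-masked assemblies, spliced transcript objects (with optional fusion
    artifacts) and uniformly tiled reads, together with truth tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
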