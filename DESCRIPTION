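Package: plateletseq
Title: Strand-Specific Characterization of an Anucleate Platelet Transcriptome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for strand-specific RNA-seq of anucleate
    platelets sequenced as long (total and rRNA-depleted) and short RNA
    preparations. Implements reference-transcript normalized expression
    (per-nucleotide read density relative to a beta-actin analog for long
    RNA and a SNORD44 analog for short RNA), detection of abundance
    distortion introduced by rRNA depletion, discovery of novel intronic
    transcripts as coverage islands in annotation-subtracted intronic
    space, sense/antisense category enrichment over exons, UTRs, repeat
    families, pseudogenes and lincRNAs, antisense-miRNA locus detection,
    and rescue of unmapped reads via lenient re-mapping and combinatorial
    exon-exon junction enumeration. Ships a synthetic-data generator with
    a planted ground-truth manifest so the full pipeline is testable at
    desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
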