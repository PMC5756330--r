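Package: tsscall
Title: Bacterial Primary-Transcriptome Analysis: TSS Detection,
    Classification, Promoter and RBS Motifs, and Operon Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects transcription start sites (TSSs) from stranded
    read-start profiles of 5'-enriched (dRNA-seq) libraries, classifies
    them by genomic context (sense, putative distal, internal, antisense,
    intergenic), revises translation start codons, measures 5'-UTRs and
    leaderless transcripts, discovers -10/-35 promoter and Shine-Dalgarno
    motifs by expectation maximization, infers operons and sub-operons
    from spanning-read counts, calls antisense and novel transcripts from
    stranded coverage, and evaluates riboswitch readthrough and
    transcription-initiation nucleotide statistics. Includes a synthetic
    bacterial transcriptome generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
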