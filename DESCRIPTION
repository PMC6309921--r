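Package: nascentr
Title: Two-Condition Analysis of Nascent Protein-Coding and lncRNA
    Transcription
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing nascent transcription of protein-coding
    genes and long noncoding RNAs (PROMPTs, eRNAs, lincRNAs) between two
    conditions. Implements single-nucleotide 3'-end signal extraction from
    paired-end mNET-seq alignments, transcription-unit set construction
    and gene pairing from a GTF annotation, library- and length-normalized
    region quantification including IP-minus-input chromatin-mark signal,
    the Chromatin Retention Index for chromatin versus nucleoplasmic RNA,
    10-bp metagene profiles, genomic categorization of R-loop (RDIP-seq)
    peaks, and a transcription-replication collision analysis over 1-kb
    replication-origin windows. A synthetic-data generator with known
    ground truth supports end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
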