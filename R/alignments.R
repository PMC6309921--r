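#' Construct a table of aligned read pairs
#'
#' The in-memory currency for paired-end alignments is a plain data frame
#' with one row per read pair, 1-based closed coordinates (the GRanges
#' convention), and the flag fields that post-alignment filtering needs.
#' Pairs can be built directly (as the synthetic-data generator does) or
#' read from a SAM file with [read_pairs_sam()].
#'
#' @param qname character, query (pair) names.
#' @param chrom character, chromosome of both mates.
#' @param r1_start,r1_end,r2_start,r2_end integer, aligned spans of read 1
#'   and read 2 (1-based, closed). `NA` for an absent mate.
#' @param r1_strand,r2_strand `"+"` or `"-"`.
#' @param proper_pair,mapped,duplicate logical flags per pair.
#' @return A `data.frame` with class `"aligned_pairs"`.
#' @export
aligned_pairs <- function(qname, chrom, r1_start, r1_end, r1_strand,
                          r2_start, r2_end, r2_strand,
                          proper_pair = TRUE, mapped = TRUE,
                          duplicate = FALSE) {
  df <- data.frame(
    qname = as.character(qname), chrom = as.character(chrom),
    r1_start = as.integer(r1_start), r1_end = as.integer(r1_end),
    r1_strand = as.character(r1_strand),
    r2_start = as.integer(r2_start), r2_end = as.integer(r2_end),
    r2_strand = as.character(r2_strand),
    proper_pair = as.logical(proper_pair), mapped = as.logical(mapped),
    duplicate = as.logical(duplicate),
    stringsAsFactors = FALSE
  )
  bad <- which(df$proper_pair & !df$mapped)
  if (length(bad) > 0L)
    stop("pair '", df$qname[bad[1]], "' is flagged proper but not mapped")
  class(df) <- c("aligned_pairs", "data.frame")
  df
}

#' Retain properly paired, mapped read pairs
#'
#' Post-alignment filtering applied to every library before signal
#' extraction: only properly paired and mapped pairs are kept (the samtools
#' `-f 3` contract).  PCR-duplicate removal is switched on for
#' nucleosome/ChIP libraries and left off for nascent-transcription
#' libraries.
#'
#' @param pairs an [aligned_pairs()] data frame.
#' @param drop_duplicates logical; also remove duplicate-flagged pairs.
#' @return The filtered data frame; the retained pair count (the library
#'   size used for all downstream normalization) is attached as
#'   `attr(, "library_size")`.
#' @export
filter_proper_pairs <- function(pairs, drop_duplicates = FALSE) {
  req <- c("qname", "chrom", "r1_start", "r2_start", "proper_pair",
           "mapped", "duplicate")
  miss <- setdiff(req, names(pairs))
  if (length(miss) > 0L)
    stop("pairs table lacks column(s): ", paste(miss, collapse = ", "))
  orphan <- which(pairs$proper_pair & (is.na(pairs$r1_start) | is.na(pairs$r2_start)))
  if (length(orphan) > 0L)
    stop("unpaired record for query '", pairs$qname[orphan[1]],
         "': proper_pair set but a mate is missing")
  keep <- pairs$proper_pair & pairs$mapped
  if (drop_duplicates) keep <- keep & !pairs$duplicate
  out <- if (all(keep)) pairs else {
    o <- pairs[keep, , drop = FALSE]
    rownames(o) <- NULL
    o
  }
  attr(out, "library_size") <- nrow(out)
  out
}

#' Write read pairs as SAM
#'
#' Serializes an [aligned_pairs()] table to a plain-text SAM file
#' (`@HD`/`@SQ` header plus two records per pair, CIGAR `<len>M`).
#' Unmapped pairs are skipped with a warning; SAM interchange is only
#' defined here for mapped pairs.
#'
#' @param pairs an [aligned_pairs()] data frame.
#' @param path output file path.
#' @param seqlengths named integer vector of chromosome lengths.
#' @return `path`, invisibly.
#' @export
write_pairs_sam <- function(pairs, path, seqlengths) {
  stopifnot(!is.null(names(seqlengths)))
  keep <- pairs$mapped & !is.na(pairs$r1_start) & !is.na(pairs$r2_start)
  if (any(!keep)) {
    warning(sum(!keep), " unmapped/incomplete pair(s) not written")
    pairs <- pairs[keep, , drop = FALSE]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                     as.integer(seqlengths)), con)
  if (nrow(pairs) == 0L) return(invisible(path))
  qn <- pairs$qname
  if (anyDuplicated(qn)) pairs$qname <- paste0(qn, ":", seq_along(qn))
  flag_common <- 1L + ifelse(pairs$proper_pair, 2L, 0L) +
    ifelse(pairs$duplicate, 1024L, 0L)
  f1 <- flag_common + 64L + ifelse(pairs$r1_strand == "-", 16L, 0L) +
    ifelse(pairs$r2_strand == "-", 32L, 0L)
  f2 <- flag_common + 128L + ifelse(pairs$r2_strand == "-", 16L, 0L) +
    ifelse(pairs$r1_strand == "-", 32L, 0L)
  tlen <- pmax(pairs$r1_end, pairs$r2_end) - pmin(pairs$r1_start, pairs$r2_start) + 1L
  sgn1 <- ifelse(pairs$r1_start <= pairs$r2_start, tlen, -tlen)
  rec1 <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t=\t%d\t%d\t*\t*",
                  pairs$qname, f1, pairs$chrom, pairs$r1_start,
                  pairs$r1_end - pairs$r1_start + 1L, pairs$r2_start, sgn1)
  rec2 <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t=\t%d\t%d\t*\t*",
                  pairs$qname, f2, pairs$chrom, pairs$r2_start,
                  pairs$r2_end - pairs$r2_start + 1L, pairs$r1_start, -sgn1)
  recs <- c(rec1, rec2)
  pos <- c(pairs$r1_start, pairs$r2_start)
  chr <- c(pairs$chrom, pairs$chrom)
  ord <- order(match(chr, names(seqlengths)), pos)
  writeLines(recs[ord], con)
  invisible(path)
}

#' Read read pairs from a SAM/BAM file
#'
#' Parses coordinate-sorted paired-end alignments through
#' Rsamtools/GenomicAlignments (SAM input is converted to BAM on the fly)
#' and returns the [aligned_pairs()] representation.  Chromosome lengths
#' from the header are attached as `attr(, "seqlengths")`.
#'
#' @param path a SAM or BAM file.
#' @return An [aligned_pairs()] data frame.
#' @export
read_pairs_sam <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = TRUE)
  } else if (!file.exists(paste0(path, ".bai"))) {
    Rsamtools::indexBam(path)
  }
  ga <- GenomicAlignments::readGAlignmentPairs(
    bam, use.names = TRUE,
    param = Rsamtools::ScanBamParam(what = "flag"),
    strandMode = 0
  )
  first <- GenomicAlignments::first(ga)
  last <- GenomicAlignments::last(ga)
  fl <- S4Vectors::mcols(first)$flag
  df <- aligned_pairs(
    qname = names(ga),
    chrom = as.character(GenomeInfoDb::seqnames(first)),
    r1_start = BiocGenerics::start(first), r1_end = BiocGenerics::end(first),
    r1_strand = as.character(BiocGenerics::strand(first)),
    r2_start = BiocGenerics::start(last), r2_end = BiocGenerics::end(last),
    r2_strand = as.character(BiocGenerics::strand(last)),
    proper_pair = bitwAnd(fl, 2L) > 0L,
    mapped = bitwAnd(fl, 4L) == 0L,
    duplicate = bitwAnd(fl, 1024L) > 0L
  )
  attr(df, "seqlengths") <- GenomeInfoDb::seqlengths(ga)
  df
}
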