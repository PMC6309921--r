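#' @import methods
#' @importClassesFrom IRanges RleList
NULL

#' SignalTrack: strand-aware genome-wide signal
#'
#' Per-base (or binned) signal stored as one run-length encoded vector per
#' chromosome and strand, with the library size (retained read pairs)
#' attached.  This is the common currency of all quantification: nascent
#' 3'-end counts, RNA-seq fragment coverage and IP/input coverage are all
#' SignalTracks.  Unstranded assays (mononucleosome/ChIP libraries) store
#' their signal on the plus slot with `stranded = FALSE`.
#'
#' @slot plus,minus [IRanges::RleList-class] signal per chromosome.
#' @slot stranded logical scalar.
#' @slot bin_size integer; 1 for single-base resolution.
#' @slot library_size numeric; retained pair count for normalization.
#' @slot label character label for reports.
#' @slot meta list of counters (e.g. skipped pairs).
#' @export
setClass("SignalTrack", representation(
  plus = "RleList", minus = "RleList", stranded = "logical",
  bin_size = "integer", library_size = "numeric", label = "character",
  meta = "list"
))

setValidity("SignalTrack", function(object) {
  if (!identical(names(object@plus), names(object@minus)))
    return("plus and minus strands cover different chromosomes")
  if (any(vapply(object@plus, function(r) any(S4Vectors::runValue(r) < 0), logical(1))) ||
      any(vapply(object@minus, function(r) any(S4Vectors::runValue(r) < 0), logical(1))))
    return("signal values must be >= 0")
  if (object@bin_size < 1L) return("bin_size must be >= 1")
  TRUE
})

#' @rdname SignalTrack-class
#' @param plus,minus RleLists of per-chromosome signal (minus may be NULL
#'   for unstranded tracks).
#' @param stranded logical.
#' @param bin_size integer bin width in bp.
#' @param library_size retained pair count.
#' @param label track label.
#' @param meta list of counters.
#' @export
SignalTrack <- function(plus, minus = NULL, stranded = !is.null(minus),
                        bin_size = 1L, library_size, label = "",
                        meta = list()) {
  if (is.null(minus)) {
    minus <- IRanges::RleList(lapply(lengths(plus), function(n)
      S4Vectors::Rle(0, n)), compress = FALSE)
    names(minus) <- names(plus)
  }
  new("SignalTrack", plus = plus, minus = minus, stranded = stranded,
      bin_size = as.integer(bin_size), library_size = as.numeric(library_size),
      label = label, meta = meta)
}

setMethod("show", "SignalTrack", function(object) {
  cat("SignalTrack", if (nzchar(object@label)) sQuote(object@label) else "",
      "\n  chromosomes:", length(object@plus),
      "| stranded:", object@stranded,
      "| bin:", object@bin_size, "bp",
      "| library:", format(object@library_size, big.mark = ","), "pairs",
      "\n  total signal:", track_total(object), "\n")
})

#' Total signal in a track
#' @param track a SignalTrack.
#' @return numeric scalar: sum over all chromosomes and strands.
#' @export
track_total <- function(track) {
  sum(vapply(track@plus, sum, numeric(1))) +
    sum(vapply(track@minus, sum, numeric(1)))
}

#' Chromosome lengths of a track (in bins)
#' @param track a SignalTrack.
#' @return named integer vector.
#' @export
track_seqlengths <- function(track) {
  out <- lengths(track@plus)
  names(out) <- names(track@plus)
  out
}

# RleList for one strand; "*" collapses both strands.
track_strand_signal <- function(track, strand = c("*", "+", "-")) {
  strand <- match.arg(strand)
  if (!track@stranded) return(track@plus)
  switch(strand,
    "+" = track@plus,
    "-" = track@minus,
    "*" = track@plus + track@minus
  )
}

# pairs -> GRanges of chosen spans with signal strand applied
pair_granges <- function(chrom, start, end, sig_strand, seqlengths) {
  unknown <- setdiff(unique(chrom), names(seqlengths))
  if (length(unknown) > 0L)
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = names(seqlengths)),
    ranges = IRanges::IRanges(start, end),
    strand = sig_strand,
    seqlengths = seqlengths
  )
}

signal_strand <- function(r1_strand, strand_mode) {
  if (strand_mode == "reverse_of_read1") opposite_strand(r1_strand)
  else r1_strand
}

#' Extract single-nucleotide nascent 3'-end signal
#'
#' The core mNET-seq reduction: every filtered read pair contributes one
#' unit of signal at the 3'-terminal aligned base of read 2 (the rightmost
#' base of a plus-strand alignment, the leftmost of a minus-strand one),
#' and the signal strand is taken from read 1.  With the default
#' `"reverse_of_read1"` convention (dUTP-style first-strand libraries) the
#' signal strand is the reverse of read 1's alignment strand.
#'
#' Total extracted signal equals the number of usable input pairs, so
#' bedGraph normalization by `library_size` is exact.
#'
#' @param pairs filtered [aligned_pairs()].
#' @param seqlengths named integer chromosome lengths.
#' @param strand_mode `"reverse_of_read1"` (default) or `"same_as_read1"`.
#' @param label track label.
#' @return A stranded [SignalTrack-class]; pairs lacking read 2 are skipped
#'   and counted in `meta$n_skipped`.
#' @export
extract_net_3prime <- function(pairs, seqlengths,
                               strand_mode = c("reverse_of_read1",
                                               "same_as_read1"),
                               label = "mNET-seq 3p") {
  strand_mode <- match.arg(strand_mode)
  skip <- is.na(pairs$r2_start)
  p <- if (any(skip)) pairs[!skip, , drop = FALSE] else pairs
  pos <- p$r2_start
  i <- p$r2_strand == "+"
  pos[i] <- p$r2_end[i]
  sig <- signal_strand(p$r1_strand, strand_mode)
  gr <- pair_granges(p$chrom, pos, pos, sig, seqlengths)
  plus <- GenomicRanges::coverage(gr[BiocGenerics::strand(gr) == "+"])
  minus <- GenomicRanges::coverage(gr[BiocGenerics::strand(gr) == "-"])
  SignalTrack(plus, minus, stranded = TRUE, library_size = nrow(p),
              label = label, meta = list(n_skipped = sum(skip)))
}

#' Fragment coverage track
#'
#' Per-base fragment-overlap coverage for RNA-seq, mononucleosome and
#' ChIP libraries.  Each pair contributes +1 over the union span of its two
#' mates.  Stranded mode assigns each fragment the library's signal strand
#' (see [extract_net_3prime()]); unstranded mode pools everything.
#'
#' @param pairs filtered [aligned_pairs()].
#' @param seqlengths named integer chromosome lengths.
#' @param stranded logical; strand-specific coverage?
#' @param strand_mode signal-strand convention (stranded mode only).
#' @param bin_size integer; `> 1` aggregates per-base coverage into
#'   fixed-width bins (bin value = summed per-base coverage).
#' @param label track label.
#' @return A [SignalTrack-class].
#' @export
coverage_track <- function(pairs, seqlengths, stranded = TRUE,
                           strand_mode = c("reverse_of_read1",
                                           "same_as_read1"),
                           bin_size = 1L, label = "coverage") {
  strand_mode <- match.arg(strand_mode)
  if (bin_size < 1L) stop("bin_size must be >= 1")
  fs <- pmin(pairs$r1_start, pairs$r2_start, na.rm = TRUE)
  fe <- pmax(pairs$r1_end, pairs$r2_end, na.rm = TRUE)
  fe <- pmin(fe, seqlengths[pairs$chrom])
  fs <- pmax(fs, 1L)
  sig <- if (stranded) signal_strand(pairs$r1_strand, strand_mode)
         else rep("*", nrow(pairs))
  gr <- pair_granges(pairs$chrom, fs, fe, sig, seqlengths)
  if (stranded) {
    plus <- GenomicRanges::coverage(gr[BiocGenerics::strand(gr) == "+"])
    minus <- GenomicRanges::coverage(gr[BiocGenerics::strand(gr) == "-"])
  } else {
    plus <- GenomicRanges::coverage(gr)
    minus <- NULL
  }
  if (bin_size > 1L) {
    plus <- bin_rlelist(plus, bin_size)
    if (!is.null(minus)) minus <- bin_rlelist(minus, bin_size)
  }
  SignalTrack(plus, minus, stranded = stranded, bin_size = bin_size,
              library_size = nrow(pairs), label = label)
}

# sum an RleList into fixed-width bins (last bin may be partial)
bin_rlelist <- function(rlel, bin_size) {
  out <- lapply(rlel, function(r) {
    n <- length(r)
    nb <- ceiling(n / bin_size)
    w <- rep(bin_size, nb)
    w[nb] <- n - (nb - 1L) * bin_size
    v <- IRanges::Views(r, IRanges::successiveIRanges(w))
    S4Vectors::Rle(IRanges::viewSums(v))
  })
  IRanges::RleList(out, compress = FALSE)
}

#' Write a track as library-size-normalized bedGraph
#'
#' Values are scaled to a fixed library size (default 100 million pairs):
#' written value = raw signal x `scale_to / library_size`.
#'
#' @param track a [SignalTrack-class] at base resolution.
#' @param file_plus path for the plus-strand (or unstranded) bedGraph.
#' @param file_minus path for the minus strand (stranded tracks).
#' @param scale_to target library size for normalization.
#' @return Invisibly, the written path(s).
#' @export
write_bedgraph <- function(track, file_plus, file_minus = NULL,
                           scale_to = 1e8) {
  if (track@bin_size != 1L) stop("bedGraph export requires bin_size 1")
  nf <- scale_to / track@library_size
  wr <- function(rlel, path) {
    gr <- GenomicRanges::bindAsGRanges(score = rlel)
    gr <- gr[S4Vectors::mcols(gr)$score != 0]
    S4Vectors::mcols(gr)$score <- S4Vectors::mcols(gr)$score * nf
    rtracklayer::export(gr, path, format = "bedGraph")
    path
  }
  out <- wr(track@plus, file_plus)
  if (track@stranded && !is.null(file_minus))
    out <- c(out, wr(track@minus, file_minus))
  invisible(out)
}

#' Read a bedGraph pair back into a SignalTrack
#'
#' Inverse of [write_bedgraph()]: values are de-normalized with the given
#' library size, so a write/read round trip reproduces the raw track to
#' floating-point precision.
#'
#' @param file_plus,file_minus bedGraph paths (minus optional).
#' @param library_size the library size the values were normalized with.
#' @param seqlengths named integer chromosome lengths.
#' @param scale_to the normalization target used at write time.
#' @param label track label.
#' @return A [SignalTrack-class].
#' @export
read_bedgraph <- function(file_plus, file_minus = NULL, library_size,
                          seqlengths, scale_to = 1e8, label = "") {
  nf <- scale_to / library_size
  rd <- function(path) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
    GenomicRanges::coverage(gr, weight = S4Vectors::mcols(gr)$score / nf)
  }
  plus <- rd(file_plus)
  minus <- if (!is.null(file_minus)) rd(file_minus) else NULL
  SignalTrack(plus, minus, stranded = !is.null(minus),
              library_size = library_size, label = label)
}

#' Read a BED file of intervals
#'
#' @param path a BED file (3-6 columns).
#' @return A `GRanges`.
#' @export
read_bed <- function(path) rtracklayer::import(path, format = "BED")

#' Read peaks with summits
#'
#' ENCODE narrowPeak files carry the summit as an offset from the peak
#' start (10th column); plain BED peaks get their midpoint as summit.  The
#' absolute 1-based summit position is returned in the `summit` metadata
#' column.
#'
#' @param path peak file.
#' @param format `"narrowPeak"` or `"bed"` (default guessed from the file
#'   extension).
#' @return A `GRanges` with a `summit` metadata column.
#' @export
read_peaks <- function(path, format = c("auto", "narrowPeak", "bed")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("narrowPeak$", path, ignore.case = TRUE))
      "narrowPeak" else "bed"
  if (format == "narrowPeak") {
    gr <- rtracklayer::import(
      path, format = "BED",
      extraCols = c(signalValue = "numeric", pValue = "numeric",
                    qValue = "numeric", peak = "integer"))
    S4Vectors::mcols(gr)$summit <- BiocGenerics::start(gr) +
      S4Vectors::mcols(gr)$peak
  } else {
    gr <- rtracklayer::import(path, format = "BED")
    S4Vectors::mcols(gr)$summit <- as.integer(
      floor((BiocGenerics::start(gr) + BiocGenerics::end(gr)) / 2))
  }
  gr
}
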