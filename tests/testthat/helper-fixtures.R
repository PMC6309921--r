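# Shared fixtures, all built in code.

toy_seqlengths <- c(chrA = 100000L, chrB = 80000L)

# A SignalTrack with the given constant value over each region of `gr`
# (zero elsewhere), on the strand of each region ("*" -> both strands).
track_from_regions <- function(gr, values, seqlengths = toy_seqlengths,
                               library_size = 1e8, stranded = TRUE) {
  mk <- function(strands) {
    sel <- as.character(GenomicRanges::strand(gr)) %in% strands
    g <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr)[sel],
                                IRanges::ranges(gr)[sel],
                                seqlengths = seqlengths)
    GenomicRanges::coverage(g, weight = values[sel])
  }
  if (stranded)
    SignalTrack(mk(c("+", "*")), mk(c("-", "*")), stranded = TRUE,
                library_size = library_size)
  else
    SignalTrack(mk(c("+", "-", "*")), stranded = FALSE,
                library_size = library_size)
}

# hand-built pair table: n pairs with given 3' positions / signal strands
pairs_at <- function(chrom, pos3, sig_strand, read_len = 50L,
                     frag_len = 120L) {
  plus <- sig_strand == "+"
  r2_start <- ifelse(plus, pos3 - read_len + 1L, pos3)
  r2_end <- ifelse(plus, pos3, pos3 + read_len - 1L)
  r1_start <- ifelse(plus, pos3 - frag_len + 1L, pos3 + frag_len - read_len)
  aligned_pairs(
    qname = paste0("q", seq_along(pos3)), chrom = chrom,
    r1_start = r1_start, r1_end = r1_start + read_len - 1L,
    r1_strand = ifelse(plus, "-", "+"),
    r2_start = r2_start, r2_end = r2_end,
    r2_strand = sig_strand)
}

# small deterministic TU set: three genes on chrA, one on chrB
tiny_tus <- function() {
  gr <- GenomicRanges::GRanges(
    c("chrA", "chrA", "chrA", "chrB"),
    IRanges::IRanges(c(10001, 30001, 60001, 5001),
                     c(15000, 42000, 61000, 9000)),
    strand = c("+", "-", "+", "-"),
    gene_id = c("g1", "g2", "g3", "g4"),
    gene_name = c("G1", "G2", "G3", "G4"),
    biotype = c("protein_coding", "protein_coding", "lincRNA",
                "protein_coding"),
    seqlengths = toy_seqlengths)
  mc <- S4Vectors::mcols(gr)
  mc$tss <- ifelse(as.character(GenomicRanges::strand(gr)) == "+",
                   GenomicRanges::start(gr), GenomicRanges::end(gr))
  mc$tes <- ifelse(as.character(GenomicRanges::strand(gr)) == "+",
                   GenomicRanges::end(gr), GenomicRanges::start(gr))
  mc$exons <- IRanges::IRangesList(
    IRanges::IRanges(c(10001, 13001), c(11000, 15000)),
    IRanges::IRanges(c(30001, 36001, 41001), c(32000, 38000, 42000)),
    IRanges::IRanges(60001, 61000),
    IRanges::IRanges(5001, 9000))
  mc$n_exons <- lengths(mc$exons)
  S4Vectors::mcols(gr) <- mc
  gr
}

# brute-force per-base sum over a region from a track (oracle)
oracle_basecount <- function(track, chrom, start, end, strand = "*") {
  r <- if (strand == "+") track@plus[[chrom]]
       else if (strand == "-") track@minus[[chrom]]
       else track@plus[[chrom]] + track@minus[[chrom]]
  sum(as.numeric(r)[start:end])
}
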