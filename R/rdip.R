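#' Assign strands to R-loop peaks from strand-specific reads
#'
#' Each peak takes the strand carrying the majority of the overlapping
#' strand-specific read signal; exact ties (including peaks with no
#' overlapping signal) are left unstranded (`*`).
#'
#' @param peaks a `GRanges` of called peaks.
#' @param track a stranded base-resolution [SignalTrack-class] of the
#'   RDIP reads.
#' @return `peaks` with strand set and metadata columns `plus_signal`,
#'   `minus_signal`; the number of signal-free peaks is attached as
#'   `attr(, "n_no_signal")`.
#' @export
assign_peak_strand <- function(peaks, track) {
  if (!track@stranded) stop("strand assignment needs a stranded track")
  ps <- region_basecount(track, peaks, strand_mode = "plus")
  ms <- region_basecount(track, peaks, strand_mode = "minus")
  strd <- ifelse(ps > ms, "+", ifelse(ms > ps, "-", "*"))
  out <- peaks
  BiocGenerics::strand(out) <- strd
  S4Vectors::mcols(out)$plus_signal <- ps
  S4Vectors::mcols(out)$minus_signal <- ms
  attr(out, "n_no_signal") <- sum(ps == 0 & ms == 0)
  out
}

peak_summits <- function(peaks) {
  s <- S4Vectors::mcols(peaks)$summit
  if (is.null(s))
    s <- as.integer(floor((BiocGenerics::start(peaks) +
                             BiocGenerics::end(peaks)) / 2))
  GenomicRanges::GRanges(GenomeInfoDb::seqnames(peaks),
                         IRanges::IRanges(s, s),
                         seqinfo = GenomeInfoDb::seqinfo(peaks))
}

#' Categorize peaks into genomic compartments
#'
#' Partitions peaks among `exon`, `intron`, `upstream` (within
#' `upstream_bp` of a TSS), `downstream` (within `downstream_bp` of a
#' TES) and `distal` (everything else).  Membership is decided at the
#' peak summit with precedence exon > intron > upstream > downstream >
#' distal, so every peak receives exactly one category.  Upstream and
#' downstream flanks follow each TU's orientation.
#'
#' @param peaks a `GRanges` with a `summit` metadata column (see
#'   [read_peaks()]); otherwise the midpoint is used.
#' @param tus TU `GRanges` from [extract_tus()] (with `exons`).
#' @param upstream_bp,downstream_bp flank widths (bp).
#' @return `peaks` with a `category` metadata column (factor).
#' @export
categorize_peaks <- function(peaks, tus, upstream_bp = 2000,
                             downstream_bp = 2000) {
  smt <- peak_summits(peaks)
  exons <- tu_exon_granges(tus)
  up <- GenomicRanges::trim(GenomicRanges::flank(tus, upstream_bp, start = TRUE))
  dn <- GenomicRanges::trim(GenomicRanges::flank(tus, downstream_bp, start = FALSE))

  cat <- rep("distal", length(peaks))
  in_dn <- IRanges::overlapsAny(smt, dn, ignore.strand = TRUE)
  in_up <- IRanges::overlapsAny(smt, up, ignore.strand = TRUE)
  in_tu <- IRanges::overlapsAny(smt, tus, ignore.strand = TRUE)
  in_ex <- IRanges::overlapsAny(smt, exons, ignore.strand = TRUE)
  cat[in_dn] <- "downstream"
  cat[in_up] <- "upstream"
  cat[in_tu] <- "intron"
  cat[in_ex] <- "exon"
  out <- peaks
  S4Vectors::mcols(out)$category <-
    factor(cat, levels = c("exon", "intron", "upstream", "downstream",
                           "distal"))
  out
}

tu_exon_granges <- function(tus) {
  exl <- S4Vectors::mcols(tus)$exons
  if (is.null(exl)) return(GenomicRanges::granges(tus))
  n <- lengths(exl)
  GenomicRanges::GRanges(
    rep(GenomeInfoDb::seqnames(tus), n),
    BiocGenerics::unlist(exl, use.names = FALSE),
    strand = rep(BiocGenerics::strand(tus), n),
    seqinfo = GenomeInfoDb::seqinfo(tus))
}

#' Category lengths of the genomic compartments
#'
#' Total non-redundant bp per category (same precedence as
#' [categorize_peaks()]), for size-normalized peak densities.
#'
#' @param tus TU `GRanges` from [extract_tus()].
#' @param genome_size total genome length in bp (for the distal
#'   remainder).
#' @param upstream_bp,downstream_bp flank widths (bp).
#' @return Named numeric vector of lengths (bp).
#' @export
category_lengths <- function(tus, genome_size, upstream_bp = 2000,
                             downstream_bp = 2000) {
  red <- function(gr) IRanges::reduce(gr, ignore.strand = TRUE)
  bp <- function(gr) sum(as.numeric(BiocGenerics::width(gr)))
  exons <- red(tu_exon_granges(tus))
  tu_all <- red(GenomicRanges::granges(tus))
  up <- red(GenomicRanges::trim(GenomicRanges::flank(tus, upstream_bp, TRUE)))
  dn <- red(GenomicRanges::trim(GenomicRanges::flank(tus, downstream_bp, FALSE)))
  l_ex <- bp(exons)
  l_in <- bp(tu_all) - bp(GenomicRanges::intersect(tu_all, exons))
  genic_plus_up <- red(c(tu_all, up))
  genic_all <- red(c(tu_all, up, dn))
  l_up <- bp(genic_plus_up) - bp(tu_all)
  l_dn <- bp(genic_all) - bp(genic_plus_up)
  c(exon = l_ex, intron = l_in, upstream = l_up, downstream = l_dn,
    distal = genome_size - bp(genic_all))
}

#' Peak distribution over genomic categories
#'
#' Raw fractions per category (summing to 1), or size-normalized
#' densities: peaks per bp of category, rescaled to sum to 1, so a small
#' compartment attracting many peaks stands out.
#'
#' @param categorized_peaks output of [categorize_peaks()].
#' @param category_lengths named lengths from [category_lengths()]
#'   (required when normalizing).
#' @param normalize_by_size logical.
#' @return Named numeric vector of fractions.
#' @export
category_distribution <- function(categorized_peaks, category_lengths = NULL,
                                  normalize_by_size = FALSE) {
  if (length(categorized_peaks) == 0L) stop("empty peak set")
  cat <- S4Vectors::mcols(categorized_peaks)$category
  if (is.null(cat)) stop("peaks have not been categorized")
  counts <- table(cat)
  frac <- as.numeric(counts) / length(categorized_peaks)
  names(frac) <- names(counts)
  if (!normalize_by_size) return(frac)
  if (is.null(category_lengths)) stop("category_lengths required")
  if (any(category_lengths[names(frac)] <= 0))
    stop("category lengths must be > 0 when normalizing")
  dens <- as.numeric(counts) / category_lengths[names(frac)]
  out <- dens / sum(dens)
  names(out) <- names(frac)
  out
}

#' Summit co-location between two peak sets
#'
#' The fraction of A summits lying within `window_bp` of any B summit,
#' with an empirical null built by repositioning the A summits uniformly
#' at random on their own chromosomes `n_random` times.  Used to ask
#' whether R-loop peaks and DNA-damage (gamma-H2AX) peaks coincide.
#'
#' @param peaks_a,peaks_b `GRanges` with `summit` columns.
#' @param window_bp colocation window (bp).
#' @param n_random number of random repositionings.
#' @param seed RNG seed for the null.
#' @return A list: `observed`, `null` (vector), `p_value` (empirical,
#'   upper tail).
#' @export
summit_overlap <- function(peaks_a, peaks_b, window_bp, n_random = 100,
                           seed = 1L) {
  if (length(peaks_a) == 0L || length(peaks_b) == 0L)
    stop("both peak sets must be non-empty")
  sl <- GenomeInfoDb::seqlengths(peaks_a)
  if (any(is.na(sl))) stop("peaks_a needs seqlengths for the random control")
  if (window_bp >= min(sl)) stop("window must be smaller than every chromosome")
  sa <- peak_summits(peaks_a); sb <- peak_summits(peaks_b)
  frac_near <- function(a) {
    h <- GenomicRanges::distanceToNearest(a, sb, ignore.strand = TRUE)
    d <- S4Vectors::mcols(h)$distance
    sum(d <= window_bp) / length(a)
  }
  observed <- frac_near(sa)
  chr <- as.character(GenomeInfoDb::seqnames(sa))
  null <- with_seed(seed, vapply(seq_len(n_random), function(i) {
    pos <- vapply(sl[chr], function(L) sample.int(L, 1L), integer(1))
    frac_near(GenomicRanges::GRanges(chr, IRanges::IRanges(pos, pos),
                                     seqlengths = sl))
  }, numeric(1)))
  list(observed = observed, null = null,
       p_value = (1 + sum(null >= observed)) / (n_random + 1))
}
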