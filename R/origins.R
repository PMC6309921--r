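#' Classify replication origins as genic or intergenic
#'
#' An origin window is intergenic when it overlaps no annotated TU span on
#' either strand.  Only intergenic origins enter the
#' transcription-replication collision analysis.
#'
#' @param origins `GRanges` of 1-kb origin windows (other widths accepted
#'   with a warning).
#' @param tus TU `GRanges` from [extract_tus()].
#' @return `origins` with a logical `is_intergenic` metadata column.
#' @export
classify_origins <- function(origins, tus) {
  if (any(BiocGenerics::width(origins) != 1000L))
    warning("origin window(s) not 1 kb wide; proceeding anyway")
  out <- origins
  S4Vectors::mcols(out)$is_intergenic <-
    !IRanges::overlapsAny(origins, tus, ignore.strand = TRUE)
  out
}

#' Quantify Pol II signal over origin windows in two conditions
#'
#' Total nascent-transcription signal (both strands summed) over each
#' origin window, normalized to 100 million pairs and window length, in
#' the control and depleted conditions.  Origins with a positive signal in
#' at least one condition are flagged `positive_any`; downstream
#' fold-change analysis is restricted to those.
#'
#' @param origins `GRanges` of origin windows.
#' @param track_ctrl,track_depleted stranded [SignalTrack-class]s.
#' @return `origins` with `signal_ctrl`, `signal_depleted`,
#'   `positive_any` metadata columns.
#' @export
origin_signal <- function(origins, track_ctrl, track_depleted) {
  if (missing(track_ctrl) || missing(track_depleted))
    stop("both condition tracks are required")
  q <- function(track) {
    cnt <- region_basecount(track, origins, strand_mode = "both")
    cnt * (1e8 / track@library_size) / BiocGenerics::width(origins)
  }
  out <- origins
  S4Vectors::mcols(out)$signal_ctrl <- q(track_ctrl)
  S4Vectors::mcols(out)$signal_depleted <- q(track_depleted)
  S4Vectors::mcols(out)$positive_any <-
    S4Vectors::mcols(out)$signal_ctrl > 0 |
    S4Vectors::mcols(out)$signal_depleted > 0
  out
}

#' Flag origins with induced Pol II signal
#'
#' An origin is induced when its depleted-condition signal is at least
#' `fold` times its control signal (boundary inclusive).  Zero control
#' signal is replaced by half the smallest positive control value, so a
#' fold change is always defined for `positive_any` origins.
#'
#' @param origins output of [origin_signal()].
#' @param fold fold-change threshold (> 0).
#' @return `origins` with `fold_change` and `induced_2x` metadata columns
#'   (`induced_2x` is `FALSE` for origins failing `positive_any`).
#' @export
flag_induced <- function(origins, fold = 2.0) {
  if (fold <= 0) stop("fold must be > 0")
  mc <- S4Vectors::mcols(origins)
  if (is.null(mc$signal_ctrl)) stop("run origin_signal() first")
  ctrl <- mc$signal_ctrl
  pseudo <- half_min_positive(ctrl)
  ctrl[ctrl <= 0] <- pseudo
  fc <- mc$signal_depleted / ctrl
  out <- origins
  S4Vectors::mcols(out)$fold_change <- fc
  S4Vectors::mcols(out)$induced_2x <- mc$positive_any & !is.na(fc) & fc >= fold
  out
}

#' Nearest noncoding RNA per origin
#'
#' Edge-to-edge distance from each origin window to the nearest PROMPT
#' and the nearest eRNA; neighbors farther than `max_dist` are not
#' recorded.  Origins with a neighbor of either class within `max_dist`
#' are flagged `near_ncrna`.
#'
#' @param origins `GRanges` of origin windows.
#' @param prompts,ernas `GRanges` of PROMPT TUs and eRNA centers.
#' @param max_dist maximum recorded distance (bp).
#' @return `origins` with `prompt_id`, `prompt_dist`, `erna_id`,
#'   `erna_dist` (NA beyond `max_dist`) and `near_ncrna`.
#' @export
nearest_ncrna <- function(origins, prompts, ernas, max_dist = 100000) {
  near <- function(set, ids) {
    d <- rep(NA_real_, length(origins))
    id <- rep(NA_character_, length(origins))
    if (length(set) > 0L) {
      h <- GenomicRanges::distanceToNearest(origins, set, ignore.strand = TRUE)
      qi <- S4Vectors::queryHits(h)
      dist <- S4Vectors::mcols(h)$distance
      ok <- dist <= max_dist
      d[qi[ok]] <- dist[ok]
      id[qi[ok]] <- ids[S4Vectors::subjectHits(h)][ok]
    }
    list(d = d, id = id)
  }
  p <- near(prompts, prompt_ids(prompts))
  e <- near(ernas, S4Vectors::mcols(ernas)$gene_id %||%
              paste0("eRNA_", seq_along(ernas)))
  out <- origins
  S4Vectors::mcols(out)$prompt_id <- p$id
  S4Vectors::mcols(out)$prompt_dist <- p$d
  S4Vectors::mcols(out)$erna_id <- e$id
  S4Vectors::mcols(out)$erna_dist <- e$d
  S4Vectors::mcols(out)$near_ncrna <- !is.na(p$d) | !is.na(e$d)
  out
}

#' Delimit depletion-induced lncRNA extensions
#'
#' For each lncRNA, walks downstream of its TSS (in the direction of
#' transcription) through the depleted-condition track and finds the
#' farthest point reachable where the library-normalized per-base signal
#' is at least `min_signal` and exceeds the control track, allowing
#' signal gaps up to `max_gap` bp.  The returned interval is the union of
#' the annotated span and the detected extension.
#'
#' @param track_depleted,track_ctrl stranded base-resolution
#'   [SignalTrack-class]s.
#' @param lncrnas stranded `GRanges` of annotated lncRNA spans.
#' @param min_signal minimum normalized per-base signal (units of signal
#'   per 100 million pairs).
#' @param max_gap largest tolerated signal gap (bp).
#' @param max_extension scan horizon downstream of the TSS (bp).
#' @return A `GRanges` parallel to `lncrnas` with `extension_bp` (bp
#'   gained beyond the annotated span).
#' @export
define_extended_lncrna <- function(track_depleted, track_ctrl, lncrnas,
                                   min_signal = 1, max_gap = 500,
                                   max_extension = 200000) {
  sl <- track_seqlengths(track_depleted)
  nf_dep <- 1e8 / track_depleted@library_size
  nf_ctl <- 1e8 / track_ctrl@library_size
  chr <- as.character(GenomeInfoDb::seqnames(lncrnas))
  strd <- as.character(BiocGenerics::strand(lncrnas))
  st <- BiocGenerics::start(lncrnas); en <- BiocGenerics::end(lncrnas)
  new_st <- st; new_en <- en
  ext <- integer(length(lncrnas))
  for (i in seq_along(lncrnas)) {
    L <- sl[[chr[i]]]
    fwd <- strd[i] != "-"
    tss <- if (fwd) st[i] else en[i]
    lo <- if (fwd) tss else max(1L, tss - max_extension)
    hi <- if (fwd) min(L, tss + max_extension) else tss
    dep <- as.numeric(S4Vectors::window(
      track_strand_signal(track_depleted, strd[i])[[chr[i]]], lo, hi)) * nf_dep
    ctl <- as.numeric(S4Vectors::window(
      track_strand_signal(track_ctrl, strd[i])[[chr[i]]], lo, hi)) * nf_ctl
    ok <- dep >= min_signal & dep > ctl
    if (!fwd) ok <- rev(ok)        # index 1 = TSS, increasing downstream
    r <- rle(ok)                   # walk runs, stop at a gap > max_gap
    reach <- 0L; pos <- 0L
    for (k in seq_along(r$lengths)) {
      if (r$values[k]) { pos <- pos + r$lengths[k]; reach <- pos }
      else {
        if (r$lengths[k] > max_gap) break
        pos <- pos + r$lengths[k]
      }
    }
    end_pos <- if (fwd) tss + reach - 1L else tss - reach + 1L
    if (reach > 0L) {
      if (fwd) new_en[i] <- max(en[i], end_pos)
      else new_st[i] <- min(st[i], end_pos)
    }
    ext[i] <- (new_en[i] - new_st[i]) - (en[i] - st[i])
  }
  GenomicRanges::GRanges(chr, IRanges::IRanges(new_st, new_en),
                         strand = strd,
                         gene_id = prompt_ids(lncrnas),
                         extension_bp = ext,
                         seqlengths = sl)
}

#' Fraction of origins overlapping extended lncRNA
#'
#' @param origins `GRanges` of origin windows (typically the near-ncRNA
#'   subset).
#' @param extended_intervals output of [define_extended_lncrna()].
#' @return Numeric scalar: the fraction of origins whose window
#'   intersects any extended interval.
#' @export
origin_lncrna_overlap <- function(origins, extended_intervals) {
  if (length(origins) == 0L) stop("empty origin set")
  mean(IRanges::overlapsAny(origins, extended_intervals,
                            ignore.strand = TRUE))
}

#' Origin report table
#'
#' One row per origin with every computed column, ready to write as TSV.
#'
#' @param origins a fully annotated origin `GRanges`.
#' @return A data frame.
#' @export
origin_report <- function(origins) {
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(origins)),
    start = BiocGenerics::start(origins),
    end = BiocGenerics::end(origins),
    stringsAsFactors = FALSE)
  cbind(df, as.data.frame(S4Vectors::mcols(origins)))
}
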