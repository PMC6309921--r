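#' Total read base count over regions
#'
#' Sums the per-base track signal over each region.  For nascent 3'-end
#' tracks this is the read count; for coverage tracks it is the summed
#' fragment coverage (the `samtools bedcov` quantity).
#'
#' @param track a [SignalTrack-class] at base resolution.
#' @param regions a `GRanges` (regions are clipped to chromosome ends).
#' @param strand_mode `"region"` (use each region's strand; `*` pools
#'   both), `"both"`, `"plus"` or `"minus"`.  Unstranded tracks always
#'   pool.
#' @return Numeric vector, one value per region.
#' @export
region_basecount <- function(track, regions,
                             strand_mode = c("region", "both", "plus",
                                             "minus")) {
  strand_mode <- match.arg(strand_mode)
  if (track@bin_size != 1L)
    stop("region_basecount requires a base-resolution track")
  sl <- track_seqlengths(track)
  chr <- as.character(GenomeInfoDb::seqnames(regions))
  unknown <- setdiff(unique(chr), names(sl))
  if (length(unknown) > 0L)
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))

  st <- pmax(BiocGenerics::start(regions), 1L)
  en <- pmin(BiocGenerics::end(regions), sl[chr])
  ok <- st <= en

  sum_one <- function(rlel, idx) {
    out <- numeric(length(idx))
    sp <- split(seq_along(idx), chr[idx])
    for (cn in names(sp)) {
      ii <- sp[[cn]]
      v <- IRanges::Views(rlel[[cn]], IRanges::IRanges(st[idx[ii]], en[idx[ii]]))
      out[ii] <- IRanges::viewSums(v)
    }
    out
  }
  res <- numeric(length(regions))
  idx <- which(ok)
  if (length(idx) == 0L) return(res)
  if (!track@stranded || strand_mode == "both") {
    res[idx] <- sum_one(track_strand_signal(track, "*"), idx)
  } else if (strand_mode == "plus") {
    res[idx] <- sum_one(track@plus, idx)
  } else if (strand_mode == "minus") {
    res[idx] <- sum_one(track@minus, idx)
  } else {
    rstr <- as.character(BiocGenerics::strand(regions))
    for (s in c("+", "-")) {
      ii <- idx[rstr[idx] == s]
      if (length(ii) > 0L)
        res[ii] <- sum_one(if (s == "+") track@plus else track@minus, ii)
    }
    ii <- idx[rstr[idx] == "*"]
    if (length(ii) > 0L)
      res[ii] <- sum_one(track_strand_signal(track, "*"), ii)
  }
  res
}

#' Library- and length-normalized region quantification
#'
#' The standard unit used throughout: raw base count scaled to a library
#' of 100 million pairs and divided by region length in bp, i.e.
#' `value = count * (1e8 / library_size) / length_bp`, reported with its
#' log2.  Zero counts yield `value = 0` and `log2_value = NA`; turning
#' nonpositive values into a usable pseudo-value is the job of the
#' imputation step ([ip_minus_input_quant()]) or of the ratio functions.
#'
#' @param count numeric vector of raw base counts.
#' @param library_size library size(s) in pairs.
#' @param length_bp region length(s) in bp.
#' @param sample sample label(s).
#' @return A data frame (`region_quant`): `sample`, `raw_base_count`,
#'   `norm_factor`, `length_bp`, `value`, `log2_value`, `imputed`.
#' @export
normalize_quant <- function(count, library_size, length_bp, sample = "") {
  if (any(library_size <= 0)) stop("library_size must be > 0")
  if (any(length_bp <= 0)) stop("length_bp must be > 0")
  nf <- 1e8 / library_size
  value <- count * nf / length_bp
  df <- data.frame(
    sample = sample, raw_base_count = count, norm_factor = nf,
    length_bp = as.integer(length_bp), value = value,
    log2_value = ifelse(value > 0, log2(value), NA_real_),
    imputed = FALSE, stringsAsFactors = FALSE)
  class(df) <- c("region_quant", "data.frame")
  df
}

#' IP-minus-input chromatin-mark quantification
#'
#' For mononucleosome/ChIP data the input signal is subtracted from the IP
#' signal after each is scaled to 100 million pairs, and the difference is
#' divided by region length.  Regions with a nonpositive value in every
#' sample are dropped; remaining nonpositive values are set to half the
#' smallest positive value of their sample and flagged as imputed, so logs
#' are always defined.
#'
#' @param ip_counts,input_counts numeric matrices (regions x samples) of
#'   raw base counts; vectors are treated as one sample.
#' @param ip_lib,input_lib per-sample library sizes.
#' @param length_bp per-region lengths (bp).
#' @return A list of class `"ip_quant"`: `value` and `log2_value`
#'   (matrices over kept regions), `imputed` (logical matrix), `kept`
#'   (indices of retained regions), `n_dropped`.
#' @export
ip_minus_input_quant <- function(ip_counts, input_counts, ip_lib, input_lib,
                                 length_bp) {
  ip <- as.matrix(ip_counts); inp <- as.matrix(input_counts)
  stopifnot(identical(dim(ip), dim(inp)))
  ns <- ncol(ip)
  if (any(ip_lib <= 0) || any(input_lib <= 0)) stop("library sizes must be > 0")
  if (any(length_bp <= 0)) stop("length_bp must be > 0")
  ip_lib <- rep_len(ip_lib, ns); input_lib <- rep_len(input_lib, ns)

  val <- sweep(ip, 2, 1e8 / ip_lib, `*`) -
    sweep(inp, 2, 1e8 / input_lib, `*`)
  val <- val / length_bp

  keep <- rowSums(val > 0) > 0
  if (!any(keep)) stop("no region has a positive signal in any sample")
  val <- val[keep, , drop = FALSE]
  imputed <- val <= 0
  for (j in seq_len(ns)) {
    nonpos <- imputed[, j]
    if (any(nonpos)) val[nonpos, j] <- half_min_positive(val[, j])
  }
  structure(list(value = val, log2_value = log2(val), imputed = imputed,
                 kept = which(keep), n_dropped = sum(!keep)),
            class = "ip_quant")
}

#' Quantification windows per region class
#'
#' The per-class windows used for all boxplot/scatter quantification, all
#' strand-aware (extension follows the direction of transcription):
#' PROMPTs from the TSS to TSS + 3 kb; eRNAs from 2 kb upstream to 2 kb
#' downstream of their center; lincRNA, coding (intron-containing and
#' intronless) and snRNA genes over their full TU (TSS to TES); and the
#' 5-kb PROMPT window used by the Chromatin Retention Index.
#'
#' @param regions a `GRanges` (TUs, PROMPT TUs, or eRNA centers).
#' @param region_class one of `"PROMPT"`, `"eRNA"`, `"lincRNA"`,
#'   `"coding"`, `"intronless"`, `"snRNA"`, `"CRI_PROMPT"`.
#' @return A `GRanges` of quantification windows, clipped to chromosome
#'   bounds when seqlengths are known.
#' @export
class_window <- function(regions, region_class) {
  win <- switch(
    region_class,
    PROMPT = GenomicRanges::promoters(regions, upstream = 0, downstream = 3000),
    CRI_PROMPT = GenomicRanges::promoters(regions, upstream = 0, downstream = 5000),
    eRNA = {
      mid <- as.integer(floor((BiocGenerics::start(regions) +
                                 BiocGenerics::end(regions)) / 2))
      GenomicRanges::GRanges(GenomeInfoDb::seqnames(regions),
                             IRanges::IRanges(mid - 2000L, mid + 1999L),
                             strand = BiocGenerics::strand(regions),
                             seqinfo = GenomeInfoDb::seqinfo(regions))
    },
    lincRNA = , coding = , intronless = , snRNA = GenomicRanges::granges(regions),
    stop("unknown region class: ", region_class)
  )
  S4Vectors::mcols(win) <- S4Vectors::mcols(regions)
  GenomicRanges::trim(win)
}

#' Chromatin Retention Index
#'
#' CRI = log2(chromatin / nucleoplasm) of the normalized signal over the
#' 5-kb PROMPT window (TSS to TSS + 5 kb), each fraction normalized to its
#' own library size and to the window length.  A positive CRI means the
#' transcript stays on chromatin.  Nonpositive values on either side are
#' replaced by half the smallest positive value of that fraction and
#' flagged.
#'
#' @param chromatin_value,nucleoplasm_value normalized values
#'   (e.g. `normalize_quant(...)$value`) over identical windows.
#' @param region_id optional region labels.
#' @return A data frame: `region_id`, `chromatin_value`,
#'   `nucleoplasm_value`, `cri`, `imputed`.
#' @export
chromatin_retention_index <- function(chromatin_value, nucleoplasm_value,
                                      region_id = NULL) {
  if (length(chromatin_value) != length(nucleoplasm_value))
    stop("chromatin and nucleoplasm quantifications cover different regions")
  cv <- chromatin_value; nv <- nucleoplasm_value
  imputed <- cv <= 0 | nv <= 0
  cv[cv <= 0] <- half_min_positive(chromatin_value)
  nv[nv <= 0] <- half_min_positive(nucleoplasm_value)
  data.frame(
    region_id = region_id %||% seq_along(cv),
    chromatin_value = chromatin_value,
    nucleoplasm_value = nucleoplasm_value,
    cri = log2(cv / nv), imputed = imputed,
    stringsAsFactors = FALSE)
}

#' Chromatin-mark enrichment ratio
#'
#' log2 ratio of a mark's quantification to a denominator (input or total
#' H3) over the same window, optionally further divided by the normalized
#' Pol II level to express mark density per polymerase.
#'
#' @param mark_value,denom_value normalized values over the same windows.
#' @param polii_value optional normalized Pol II values.
#' @return A data frame: `ratio` (log2), `imputed`.
#' @export
mark_ratio <- function(mark_value, denom_value, polii_value = NULL) {
  mv <- mark_value; dv <- denom_value
  imputed <- mv <= 0 | dv <= 0
  mv[mv <= 0] <- half_min_positive(mark_value)
  dv[dv <= 0] <- half_min_positive(denom_value)
  r <- log2(mv / dv)
  if (!is.null(polii_value)) {
    pv <- polii_value
    imputed <- imputed | pv <= 0
    pv[pv <= 0] <- half_min_positive(polii_value)
    r <- r / pv
  }
  data.frame(ratio = r, imputed = imputed)
}

#' Genome-wide binned track correlation
#'
#' Spearman rank correlation between tracks over fixed-width genomic bins
#' (both strands pooled), the standard sample-similarity heatmap input.
#' Bins with zero signal in every track are skipped.
#'
#' @param tracks a list of [SignalTrack-class]s on the same genome.
#' @param bin_bp bin width in bp.
#' @return A symmetric correlation matrix with track labels as dimnames.
#' @export
binned_correlation <- function(tracks, bin_bp = 10000) {
  if (length(tracks) < 2L) stop("need at least two tracks")
  sl <- track_seqlengths(tracks[[1]])
  for (t in tracks)
    if (!identical(track_seqlengths(t), sl))
      stop("tracks are not on the same genome")
  binsums <- function(track) {
    unlist(lapply(names(sl), function(cn) {
      r <- track_strand_signal(track, "*")[[cn]]
      n <- length(r); nb <- ceiling(n / bin_bp)
      w <- rep(bin_bp, nb); w[nb] <- n - (nb - 1L) * bin_bp
      IRanges::viewSums(IRanges::Views(r, IRanges::successiveIRanges(w)))
    }), use.names = FALSE)
  }
  m <- vapply(tracks, binsums, numeric(sum(ceiling(sl / bin_bp))))
  labs <- vapply(seq_along(tracks), function(i) {
    l <- tracks[[i]]@label
    if (nzchar(l)) l else paste0("track", i)
  }, character(1))
  colnames(m) <- labs
  m <- m[rowSums(m > 0) > 0, , drop = FALSE]
  if (nrow(m) < 2L) stop("fewer than 2 usable (non-zero) bins")
  stats::cor(m, method = "spearman")
}

#' Two-group comparison by Wilcoxon test
#'
#' Two-sided Wilcoxon rank-sum test (unpaired) or signed-rank test
#' (paired), the significance test used for all region-set comparisons.
#'
#' @param values_a,values_b numeric vectors (paired mode requires equal
#'   lengths).
#' @param paired logical.
#' @return A list: `statistic`, `p_value`, `method`, `n_a`, `n_b`.
#' @export
compare_groups <- function(values_a, values_b, paired = FALSE) {
  if (length(values_a) < 3L || length(values_b) < 3L)
    stop("each group needs at least 3 values")
  if (paired && length(values_a) != length(values_b))
    stop("paired comparison requires equal group sizes")
  if (length(unique(c(values_a, values_b))) == 1L)
    stop("degenerate input: all values tied")
  ht <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, paired = paired,
                       alternative = "two.sided", exact = FALSE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = ht$method, n_a = length(values_a), n_b = length(values_b))
}
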