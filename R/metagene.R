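#' Metagene profiles at 10-bp resolution
#'
#' Average signal profiles around anchor points (TSS-style) or over
#' rescaled gene bodies, computed at a fixed bin size of 10 bp (the
#' resolution used for all average profiles here).  Rows are oriented 5'
#' to 3': minus-strand anchors/regions have their bins reversed, so bin 1
#' is always the most upstream position in the direction of transcription.
#' Bins falling off a chromosome end are missing (`NA`) and excluded from
#' the mean rather than zero-filled, which would bias profile edges.
#'
#' @name metagene
#' @return A list of class `"meta_profile"`: `mode`, `bin_bp`,
#'   `upstream_bp`, `downstream_bp`, `body_bins` (scale mode), `matrix`
#'   (regions x bins), `mean_profile` (per-bin mean over non-missing
#'   rows), `n_skipped`.
NULL

# per-base signal vector for [st, en] on chromosome rle, NA outside [1, L]
window_signal <- function(rle, st, en) {
  L <- length(rle)
  lo <- max(st, 1L); hi <- min(en, L)
  v <- rep(NA_real_, en - st + 1L)
  if (lo <= hi)
    v[(lo - st + 1L):(hi - st + 1L)] <-
      as.numeric(S4Vectors::window(rle, lo, hi))
  v
}

bin_sums <- function(v, bin_bp) {
  nb <- length(v) %/% bin_bp
  m <- matrix(v, nrow = bin_bp, ncol = nb)
  cs <- colSums(m)              # NA if any base missing -> treat bin missing
  cs
}

anchor_rle <- function(track, chrom, strand, strand_mode) {
  if (!track@stranded || strand_mode == "both")
    return(track_strand_signal(track, "*")[[chrom]])
  use <- switch(strand_mode,
                sense = strand,
                antisense = opposite_strand(strand),
                stop("unknown strand_mode"))
  if (use == "-") track@minus[[chrom]] else track@plus[[chrom]]
}

#' Reference-point profile
#'
#' Binned signal around anchor points (typically TSSs), oriented by anchor
#' strand.
#'
#' @param track a base-resolution [SignalTrack-class].
#' @param anchors a `GRanges` of width-1 anchor points with strand (or a
#'   stranded `GRanges` whose TSS-side start is used).
#' @param upstream_bp,downstream_bp window extent (bp); both must be
#'   multiples of `bin_bp`.
#' @param bin_bp bin width (bp).
#' @param strand_mode `"sense"` (signal on the anchor's strand, default),
#'   `"antisense"`, or `"both"`.
#' @return See [metagene].
#' @export
reference_point_profile <- function(track, anchors, upstream_bp,
                                    downstream_bp, bin_bp = 10,
                                    strand_mode = c("sense", "antisense",
                                                    "both")) {
  strand_mode <- match.arg(strand_mode)
  if (length(anchors) == 0L) stop("no anchors supplied")
  if (upstream_bp %% bin_bp != 0 || downstream_bp %% bin_bp != 0)
    stop("window extents must be multiples of bin_bp")
  if (track@bin_size != 1L) stop("metagene profiles require base resolution")
  sl <- track_seqlengths(track)
  chr <- as.character(GenomeInfoDb::seqnames(anchors))
  strd <- as.character(BiocGenerics::strand(anchors))
  pos <- ifelse(strd == "-", BiocGenerics::end(anchors),
                BiocGenerics::start(anchors))
  nb <- (upstream_bp + downstream_bp) %/% bin_bp
  mat <- matrix(NA_real_, nrow = length(anchors), ncol = nb)
  n_off <- 0L
  for (i in seq_along(anchors)) {
    if (!chr[i] %in% names(sl)) { n_off <- n_off + 1L; next }
    rle <- anchor_rle(track, chr[i], strd[i], strand_mode)
    if (strd[i] == "-") {
      v <- window_signal(rle, pos[i] - downstream_bp + 1L, pos[i] + upstream_bp)
      v <- rev(v)
    } else {
      v <- window_signal(rle, pos[i] - upstream_bp, pos[i] + downstream_bp - 1L)
    }
    if (all(is.na(v))) n_off <- n_off + 1L
    mat[i, ] <- bin_sums(v, bin_bp)
  }
  structure(list(mode = "reference_point", bin_bp = bin_bp,
                 upstream_bp = upstream_bp, downstream_bp = downstream_bp,
                 body_bins = 0L, matrix = mat,
                 mean_profile = colMeans(mat, na.rm = TRUE),
                 n_skipped = n_off),
            class = "meta_profile")
}

#' Scaled-region (gene-body) profile
#'
#' Flanks are binned natively; each region body is linearly rescaled to
#' `body_bins` bins by interpolating the cumulative signal, which
#' conserves total body signal under rescaling.
#'
#' @param track a base-resolution [SignalTrack-class].
#' @param regions a stranded `GRanges` of gene bodies.
#' @param body_bins number of bins the body is rescaled to.
#' @param upstream_bp,downstream_bp flank extents (bp).
#' @param bin_bp bin width (bp).
#' @param strand_mode as in [reference_point_profile()].
#' @return See [metagene]; regions shorter than `body_bins` bp are skipped
#'   and counted.
#' @export
scale_regions_profile <- function(track, regions, body_bins, upstream_bp,
                                  downstream_bp, bin_bp = 10,
                                  strand_mode = c("sense", "antisense",
                                                  "both")) {
  strand_mode <- match.arg(strand_mode)
  if (upstream_bp %% bin_bp != 0 || downstream_bp %% bin_bp != 0)
    stop("flank extents must be multiples of bin_bp")
  sl <- track_seqlengths(track)
  chr <- as.character(GenomeInfoDb::seqnames(regions))
  strd <- as.character(BiocGenerics::strand(regions))
  nb_up <- upstream_bp %/% bin_bp; nb_dn <- downstream_bp %/% bin_bp
  nb <- nb_up + body_bins + nb_dn
  keep <- BiocGenerics::width(regions) >= body_bins & chr %in% names(sl)
  n_skipped <- sum(!keep)
  idx <- which(keep)
  mat <- matrix(NA_real_, nrow = length(idx), ncol = nb)
  for (r in seq_along(idx)) {
    i <- idx[r]
    st <- BiocGenerics::start(regions)[i]; en <- BiocGenerics::end(regions)[i]
    rle <- anchor_rle(track, chr[i], strd[i], strand_mode)
    v_body <- window_signal(rle, st, en)
    if (strd[i] == "-") {
      v_up <- rev(window_signal(rle, en + 1L, en + upstream_bp))
      v_dn <- rev(window_signal(rle, st - downstream_bp, st - 1L))
      v_body <- rev(v_body)
    } else {
      v_up <- window_signal(rle, st - upstream_bp, st - 1L)
      v_dn <- window_signal(rle, en + 1L, en + downstream_bp)
    }
    cum <- cumsum(ifelse(is.na(v_body), 0, v_body))
    bounds <- seq(0, length(v_body), length.out = body_bins + 1L)
    cb <- stats::approx(x = 0:length(v_body), y = c(0, cum),
                        xout = bounds)$y
    mat[r, ] <- c(if (nb_up > 0) bin_sums(v_up, bin_bp),
                  diff(cb),
                  if (nb_dn > 0) bin_sums(v_dn, bin_bp))
  }
  structure(list(mode = "scale_regions", bin_bp = bin_bp,
                 upstream_bp = upstream_bp, downstream_bp = downstream_bp,
                 body_bins = body_bins, matrix = mat,
                 mean_profile = colMeans(mat, na.rm = TRUE),
                 n_skipped = n_skipped),
            class = "meta_profile")
}

#' Write a metagene profile as tab-separated plotting data
#'
#' @param profile a `"meta_profile"`.
#' @param matrix_path,profile_path output paths (either may be `NULL`).
#' @return Invisibly, the written paths.
#' @export
write_meta_profile <- function(profile, matrix_path = NULL,
                               profile_path = NULL) {
  written <- character()
  if (!is.null(matrix_path)) {
    utils::write.table(profile$matrix, matrix_path, sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       col.names = paste0("bin", seq_len(ncol(profile$matrix))))
    written <- c(written, matrix_path)
  }
  if (!is.null(profile_path)) {
    utils::write.table(
      data.frame(bin = seq_along(profile$mean_profile),
                 mean_signal = profile$mean_profile),
      profile_path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, profile_path)
  }
  invisible(written)
}
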