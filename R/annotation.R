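#' Build transcription units from a gene annotation
#'
#' Collapses a GTF-style annotation to one transcription unit (TU) per
#' gene: the span from the most 5' transcription start site to the most 3'
#' end site over all of the gene's transcripts, with the union of all
#' transcript exons.  Biotypes are mapped onto
#' `protein_coding / lincRNA / antisense / snRNA / histone / other`;
#' histone genes are recognized among protein-coding genes by a
#' configurable gene-name prefix list, since annotations carry no histone
#' biotype.
#'
#' @param annotation a GTF file path, or a `GRanges` as returned by
#'   `rtracklayer::import(..., format = "gtf")` with `type`, `gene_id`,
#'   `transcript_id` and `gene_type`/`gene_biotype` metadata.
#' @param histone_prefixes gene-name prefixes marking replication-dependent
#'   histone genes.
#' @return A `GRanges`, one range per gene, sorted, with metadata columns
#'   `gene_id`, `gene_name`, `biotype`, `tss`, `tes`, `n_exons` and
#'   `exons` (an `IRangesList` of the merged exons).
#' @export
extract_tus <- function(annotation,
                        histone_prefixes = c("HIST", "H1-", "H2A-", "H2B-",
                                             "H3-", "H4-")) {
  gr <- annotation
  if (is.character(gr)) gr <- rtracklayer::import(gr, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  if (!"type" %in% names(mc) || !"gene_id" %in% names(mc))
    stop("annotation lacks 'type'/'gene_id' attributes; malformed GTF?")
  bt_col <- intersect(c("gene_type", "gene_biotype"), names(mc))[1]
  if (is.na(bt_col)) stop("annotation lacks a gene_type/gene_biotype attribute")
  ex <- gr[mc$type == "exon"]
  if (length(ex) == 0L) stop("annotation contains no exon records")
  exm <- S4Vectors::mcols(ex)

  gene_ids <- unique(S4Vectors::mcols(gr)$gene_id)
  f <- factor(exm$gene_id, levels = gene_ids)
  no_exon <- gene_ids[!gene_ids %in% exm$gene_id]
  if (length(no_exon) > 0L)
    warning(length(no_exon), " gene(s) without exons skipped: ",
            paste(utils::head(no_exon, 3), collapse = ", "))

  exl <- S4Vectors::split(ex, f)
  exl <- exl[lengths(exl) > 0L]
  red <- BiocGenerics::unlist(range(exl))        # per-gene span
  exons <- IRanges::reduce(S4Vectors::split(IRanges::ranges(ex),
                                            f)[names(exl)])

  strd <- as.character(BiocGenerics::strand(red))
  if (any(strd == "*")) stop("gene(s) without strand in annotation")
  st <- BiocGenerics::start(red); en <- BiocGenerics::end(red)

  first_ex <- ex[!duplicated(exm$gene_id)]
  bt0 <- as.character(S4Vectors::mcols(first_ex)[[bt_col]])
  names(bt0) <- S4Vectors::mcols(first_ex)$gene_id
  gname <- if ("gene_name" %in% names(exm)) {
    gn <- as.character(S4Vectors::mcols(first_ex)$gene_name)
    names(gn) <- S4Vectors::mcols(first_ex)$gene_id
    gn
  } else stats::setNames(names(bt0), names(bt0))

  ids <- names(exl)
  biotype <- map_biotype(bt0[ids], gname[ids], histone_prefixes)
  out <- GenomicRanges::GRanges(
    seqnames = GenomeInfoDb::seqnames(red),
    ranges = IRanges::IRanges(st, en),
    strand = strd,
    gene_id = ids,
    gene_name = unname(gname[ids]),
    biotype = biotype,
    tss = ifelse(strd == "+", st, en),
    tes = ifelse(strd == "+", en, st),
    n_exons = lengths(exons),
    seqinfo = GenomeInfoDb::seqinfo(gr)
  )
  S4Vectors::mcols(out)$exons <- exons
  BiocGenerics::sort(out)
}

tu_biotypes <- c("protein_coding", "lincRNA", "antisense", "snRNA",
                 "histone", "PROMPT", "eRNA", "other")

map_biotype <- function(raw, gene_name, histone_prefixes) {
  out <- ifelse(raw %in% tu_biotypes, raw, "other")
  is_hist <- out == "protein_coding" &
    Reduce(`|`, lapply(histone_prefixes, function(p)
      startsWith(toupper(gene_name), toupper(p))))
  out[is_hist] <- "histone"
  out
}

#' TU set report
#'
#' A named gene set together with the per-step survivor counts of the
#' filter chain that produced it.
#'
#' @param set_name character label.
#' @param members character vector of gene ids.
#' @param provenance named integer vector of survivor counts, in filter
#'   order; must be non-increasing.
#' @param details optional data frame of per-gene diagnostics.
#' @return An object of class `"tu_set_report"`.
#' @export
tu_set_report <- function(set_name, members, provenance, details = NULL) {
  assert_that(all(diff(as.integer(provenance)) <= 0L),
              "provenance counts must be non-increasing along the filter chain")
  structure(list(set_name = set_name, members = members,
                 provenance = provenance, details = details),
            class = "tu_set_report")
}

#' @export
print.tu_set_report <- function(x, ...) {
  cat("TU set", sQuote(x$set_name), "-", length(x$members), "genes\n")
  for (i in seq_along(x$provenance))
    cat(sprintf("  %-24s %d\n", names(x$provenance)[i], x$provenance[i]))
  invisible(x)
}

#' Select isolated, expressed protein-coding genes
#'
#' Builds the working set of non-overlapping protein-coding genes: a gene
#' is kept when no other annotated feature (any biotype, either strand)
#' lies within `window_bp` of its TSS or TES, and its TU is longer than
#' `min_len_bp`.  The survivors' chromatin RNA-seq coverage (normalized to
#' 100 million pairs and TU length, then log2(x+1)-transformed) is
#' clustered into `k` groups by k-means, and the `keep_top` most expressed
#' clusters are merged into the final set, discarding the silent tier.
#'
#' @param tus TU `GRanges` from [extract_tus()].
#' @param chromatin_track chromatin RNA-seq [SignalTrack-class].
#' @param window_bp exclusion window around TSS/TES (bp).
#' @param min_len_bp minimum TU length (bp, strict).
#' @param k number of k-means expression groups.
#' @param keep_top number of top expression groups retained.
#' @param seed RNG seed for the k-means restarts.
#' @return A [tu_set_report()]; `details` holds per-gene coverage and
#'   cluster assignment.
#' @export
select_nonoverlapping_coding <- function(tus, chromatin_track,
                                         window_bp = 2500,
                                         min_len_bp = 2000, k = 4,
                                         keep_top = 3, seed = 1L) {
  if (chromatin_track@library_size <= 0) stop("track library size must be > 0")
  bt <- S4Vectors::mcols(tus)$biotype
  coding <- tus[bt %in% c("protein_coding", "histone")]
  n0 <- length(tus); n1 <- length(coding)

  ext <- GenomicRanges::resize(coding,
                               width = BiocGenerics::width(coding) + 2 * window_bp,
                               fix = "center")
  ext <- GenomicRanges::trim(ext)
  hits <- GenomicRanges::countOverlaps(ext, tus, ignore.strand = TRUE)
  isolated <- coding[hits <= 1L]          # only overlap is the gene itself
  n2 <- length(isolated)

  long_enough <- isolated[BiocGenerics::width(isolated) > min_len_bp]
  n3 <- length(long_enough)
  if (n3 < k)
    stop("only ", n3, " genes survive the geometric filters; ",
         "lower k (currently ", k, ") or relax the filters")

  counts <- region_basecount(chromatin_track, long_enough,
                             strand_mode = "region")
  if (all(counts == 0)) stop("chromatin track has zero coverage on every candidate gene")
  nf <- 1e8 / chromatin_track@library_size
  cov <- counts * nf / BiocGenerics::width(long_enough)
  x <- log2(cov + 1)

  km <- with_seed(seed,
                  stats::kmeans(x, centers = k, nstart = 10,
                                algorithm = "Lloyd", iter.max = 100))
  rank_means <- tapply(x, km$cluster, mean)
  top <- as.integer(names(sort(rank_means, decreasing = TRUE)))[seq_len(keep_top)]
  keep <- km$cluster %in% top
  n4 <- sum(keep)

  tu_set_report(
    "nonoverlapping_coding",
    members = S4Vectors::mcols(long_enough)$gene_id[keep],
    provenance = c(input = n0, protein_coding = n1, isolated = n2,
                   long_enough = n3, top_expression_groups = n4),
    details = data.frame(
      gene_id = S4Vectors::mcols(long_enough)$gene_id,
      coverage = cov, log2_coverage = x, cluster = km$cluster,
      selected = keep)
  )
}

#' Select intronless protein-coding genes
#'
#' Protein-coding TUs with exactly one exon, excluding histone genes,
#' whose transcriptional regulation differs from canonical mRNAs.
#'
#' @param tus TU `GRanges` from [extract_tus()].
#' @return A [tu_set_report()].
#' @export
select_intronless <- function(tus) {
  mc <- S4Vectors::mcols(tus)
  coding <- mc$biotype %in% c("protein_coding", "histone")
  single <- coding & mc$n_exons == 1L
  keep <- single & mc$biotype != "histone"
  tu_set_report(
    "intronless_coding",
    members = mc$gene_id[keep],
    provenance = c(input = length(tus), protein_coding = sum(coding),
                   single_exon = sum(single), non_histone = sum(keep))
  )
}

#' Pair PROMPTs with their host protein-coding genes
#'
#' Each promoter upstream transcript (PROMPT) is paired with the nearest
#' protein-coding gene on the opposite strand, distance measured TSS to
#' TSS.  Ties are broken toward the gene with the smaller start
#' coordinate.  PROMPTs with no opposite-strand coding gene on their
#' chromosome are dropped with a warning.
#'
#' @param prompts `GRanges` of PROMPT TUs (stranded), with `gene_id`.
#' @param tus TU `GRanges` from [extract_tus()].
#' @return A data frame of gene pairs: `kind`, `prompt_id`, `gene_id`,
#'   `tss_distance`.
#' @export
pair_prompts <- function(prompts, tus) {
  coding <- tus[S4Vectors::mcols(tus)$biotype %in% c("protein_coding", "histone")]
  if (length(coding) == 0L) stop("no protein-coding TU available for pairing")
  p_tss <- tu_tss(prompts); g_tss <- tu_tss(coding)
  p_chr <- as.character(GenomeInfoDb::seqnames(prompts))
  g_chr <- as.character(GenomeInfoDb::seqnames(coding))
  p_str <- as.character(BiocGenerics::strand(prompts))
  g_str <- as.character(BiocGenerics::strand(coding))
  g_start <- BiocGenerics::start(coding)
  g_id <- S4Vectors::mcols(coding)$gene_id
  p_id <- prompt_ids(prompts)

  rows <- lapply(seq_along(prompts), function(i) {
    cand <- which(g_chr == p_chr[i] & g_str == opposite_strand(p_str[i]))
    if (length(cand) == 0L) return(NULL)
    d <- abs(g_tss[cand] - p_tss[i])
    best <- cand[d == min(d)]
    if (length(best) > 1L) best <- best[which.min(g_start[best])]
    data.frame(kind = "prompt_mrna", prompt_id = p_id[i],
               gene_id = g_id[best], tss_distance = min(d),
               stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0L)
    warning(dropped, " PROMPT(s) dropped: no opposite-strand coding gene ",
            "on their chromosome")
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

tu_tss <- function(gr) {
  mc <- S4Vectors::mcols(gr)
  if (!is.null(mc$tss)) return(mc$tss)
  ifelse(as.character(BiocGenerics::strand(gr)) == "+",
         BiocGenerics::start(gr), BiocGenerics::end(gr))
}

prompt_ids <- function(gr) {
  mc <- S4Vectors::mcols(gr)
  mc$gene_id %||% mc$name %||% paste0("PROMPT_", seq_along(gr))
}

#' Pair divergent mRNA-lincRNA transcription units
#'
#' Candidate pairs are a protein-coding TU and a lincRNA/antisense TU on
#' opposite strands with TSSs separated by less than `max_tss_dist`.  A
#' pair is kept only when both partners carry at least `min_reads` total
#' nascent (mNET-seq) reads in at least one of the two conditions.
#'
#' @param tus TU `GRanges` from [extract_tus()].
#' @param track_ctrl,track_depleted stranded mNET-seq
#'   [SignalTrack-class]s for the two conditions.
#' @param max_tss_dist maximum TSS-to-TSS distance (bp, strict).
#' @param min_reads minimum total read count per partner.
#' @return A data frame: `kind`, `gene_id` (mRNA), `linc_id`,
#'   `tss_distance`, read counts per partner and condition, `kept`.
#' @export
pair_mrna_lincrna <- function(tus, track_ctrl, track_depleted,
                              max_tss_dist = 3000, min_reads = 10) {
  if (missing(track_ctrl) || missing(track_depleted))
    stop("both condition tracks are required")
  mc <- S4Vectors::mcols(tus)
  coding <- tus[mc$biotype %in% c("protein_coding", "histone")]
  linc <- tus[mc$biotype %in% c("lincRNA", "antisense")]
  if (length(coding) == 0L || length(linc) == 0L)
    return(data.frame(kind = character(), gene_id = character(),
                      linc_id = character(), tss_distance = integer()))
  c_tss <- tu_tss(coding); l_tss <- tu_tss(linc)
  c_chr <- as.character(GenomeInfoDb::seqnames(coding))
  l_chr <- as.character(GenomeInfoDb::seqnames(linc))
  c_str <- as.character(BiocGenerics::strand(coding))
  l_str <- as.character(BiocGenerics::strand(linc))

  cand <- do.call(rbind, lapply(seq_along(linc), function(i) {
    j <- which(c_chr == l_chr[i] & c_str == opposite_strand(l_str[i]) &
                 abs(c_tss - l_tss[i]) < max_tss_dist)
    if (length(j) == 0L) return(NULL)
    data.frame(ci = j, li = i, tss_distance = abs(c_tss[j] - l_tss[i]))
  }))
  if (is.null(cand))
    return(data.frame(kind = character(), gene_id = character(),
                      linc_id = character(), tss_distance = integer()))
  cnt <- function(track, gr) region_basecount(track, gr, strand_mode = "region")
  m_ctrl <- cnt(track_ctrl, coding[cand$ci]); m_dep <- cnt(track_depleted, coding[cand$ci])
  l_ctrl <- cnt(track_ctrl, linc[cand$li]); l_dep <- cnt(track_depleted, linc[cand$li])
  kept <- (m_ctrl >= min_reads & l_ctrl >= min_reads) |
    (m_dep >= min_reads & l_dep >= min_reads)
  out <- data.frame(
    kind = "mrna_lincrna",
    gene_id = S4Vectors::mcols(coding)$gene_id[cand$ci],
    linc_id = S4Vectors::mcols(linc)$gene_id[cand$li],
    tss_distance = cand$tss_distance,
    mrna_reads_ctrl = m_ctrl, mrna_reads_depleted = m_dep,
    linc_reads_ctrl = l_ctrl, linc_reads_depleted = l_dep,
    kept = kept, stringsAsFactors = FALSE)
  out[order(out$gene_id, out$linc_id), , drop = FALSE]
}

#' Write a TU set as BED with its provenance table
#'
#' @param report a [tu_set_report()].
#' @param tus the TU `GRanges` the members refer to.
#' @param bed_path,provenance_path output paths.
#' @return Invisibly, the BED path.
#' @export
write_tu_set <- function(report, tus, bed_path, provenance_path = NULL) {
  sel <- tus[S4Vectors::mcols(tus)$gene_id %in% report$members]
  out <- GenomicRanges::granges(sel)
  S4Vectors::mcols(out)$name <- S4Vectors::mcols(sel)$gene_id
  S4Vectors::mcols(out)$score <- 0L
  rtracklayer::export(out, bed_path, format = "BED")
  if (!is.null(provenance_path))
    utils::write.table(
      data.frame(step = names(report$provenance),
                 surviving = as.integer(report$provenance)),
      provenance_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(bed_path)
}
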