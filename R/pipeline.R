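#' Run the full two-condition analysis on synthetic data
#'
#' Orchestrates every stage from one configuration: simulate the genome
#' and libraries, extract signal tracks, build the TU sets and gene
#' pairs, quantify every region class in both conditions, compute the
#' Chromatin Retention Index and chromatin-mark ratios, metagene
#' profiles, R-loop peak annotation and summit co-location, and the
#' replication-origin collision analysis.  All randomness derives from
#' `config$seed`, so two runs from the same configuration are
#' byte-identical.
#'
#' @param config a [sim_config()].
#' @param depths named list of library depths (pairs):
#'   `netseq`, `rnaseq`, `chip`.
#' @param outdir output directory; `NULL` keeps everything in memory.
#' @return A list of class `"nascentr_run"`: `annotation`, `tu_sets`,
#'   `pairs`, `quant` (per-class per-condition table), `cri`,
#'   `mark_ratios`, `metagene`, `rdip`, `origins`, `summary`, `log`.
#' @export
run_pipeline <- function(config = sim_config(),
                         depths = list(netseq = 3e5, rnaseq = 2e5,
                                       chip = 2e5),
                         outdir = NULL) {
  t0 <- Sys.time()
  base_seed <- config$seed
  ann <- make_annotation(config)
  sl <- ann$seqlengths

  # --- signal extraction ---------------------------------------------------
  net <- lapply(stats::setNames(c("control", "depleted"),
                                c("control", "depleted")), function(cond) {
    p <- filter_proper_pairs(simulate_netseq(
      ann, cond, depths$netseq,
      seed = base_seed + if (cond == "control") 11L else 12L))
    extract_net_3prime(p, sl, label = paste0("mNET_", cond))
  })
  rna <- lapply(stats::setNames(c("chromatin", "nucleoplasm"),
                                c("chromatin", "nucleoplasm")), function(fr) {
    p <- filter_proper_pairs(simulate_fraction_rnaseq(
      ann, fr, depths$rnaseq,
      seed = base_seed + if (fr == "chromatin") 21L else 22L))
    coverage_track(p, sl, stranded = TRUE, label = paste0("RNA_", fr))
  })
  chip <- lapply(stats::setNames(c("control", "depleted"),
                                 c("control", "depleted")), function(cond) {
    lib <- simulate_ip_input(ann, "H3K36me3", cond, depths$chip,
                             seed = base_seed +
                               if (cond == "control") 31L else 32L,
                             dup_fraction = 0.05)
    lapply(lib, function(p) {
      fp <- filter_proper_pairs(p, drop_duplicates = TRUE)
      coverage_track(fp, sl, stranded = FALSE, label = "H3K36me3")
    })
  })

  # --- TU sets and pairings ------------------------------------------------
  tus <- c(ann$genes, ann$prompts)
  nonov <- select_nonoverlapping_coding(ann$genes, rna$chromatin,
                                        seed = base_seed + 41L)
  intronless <- select_intronless(ann$genes)
  ppairs <- suppressWarnings(pair_prompts(ann$prompts, ann$genes))
  lpairs <- pair_mrna_lincrna(ann$genes, net$control, net$depleted)

  # --- quantification ------------------------------------------------------
  classes <- list(
    coding = ann$genes[S4Vectors::mcols(ann$genes)$biotype == "protein_coding" &
                         S4Vectors::mcols(ann$genes)$n_exons > 1L],
    intronless = ann$genes[S4Vectors::mcols(ann$genes)$gene_id %in%
                             intronless$members],
    lincRNA = ann$genes[S4Vectors::mcols(ann$genes)$biotype %in%
                          c("lincRNA", "antisense")],
    snRNA = ann$genes[S4Vectors::mcols(ann$genes)$biotype == "snRNA"],
    PROMPT = ann$prompts,
    eRNA = ann$ernas)
  win_class <- c(coding = "coding", intronless = "intronless",
                 lincRNA = "lincRNA", snRNA = "snRNA", PROMPT = "PROMPT",
                 eRNA = "eRNA")
  quant <- do.call(rbind, lapply(names(classes), function(cl) {
    gr <- classes[[cl]]
    if (length(gr) == 0L) return(NULL)
    win <- class_window(gr, win_class[[cl]])
    do.call(rbind, lapply(names(net), function(cond) {
      cnt <- region_basecount(net[[cond]], win, strand_mode = "region")
      q <- normalize_quant(cnt, net[[cond]]@library_size,
                           BiocGenerics::width(win), sample = cond)
      cbind(data.frame(region_id = S4Vectors::mcols(gr)$gene_id,
                       class = cl, stringsAsFactors = FALSE), q)
    }))
  }))

  wide <- merge(quant[quant$sample == "control",
                      c("region_id", "class", "value")],
                quant[quant$sample == "depleted",
                      c("region_id", "class", "value")],
                by = c("region_id", "class"),
                suffixes = c("_control", "_depleted"))
  pc <- half_min_positive(wide$value_control)
  pd <- half_min_positive(wide$value_depleted)
  wide$log2_fc <- log2(pmax(wide$value_depleted, pd) /
                         pmax(wide$value_control, pc))
  class_fc <- stats::aggregate(log2_fc ~ class, wide, stats::median)

  # --- CRI -----------------------------------------------------------------
  cri_win <- class_window(ann$prompts, "CRI_PROMPT")
  cri_q <- lapply(rna, function(track) {
    cnt <- region_basecount(track, cri_win, strand_mode = "region")
    cnt * (1e8 / track@library_size) / BiocGenerics::width(cri_win)
  })
  cri <- chromatin_retention_index(
    cri_q$chromatin, cri_q$nucleoplasm,
    region_id = S4Vectors::mcols(ann$prompts)$gene_id)

  # --- chromatin-mark ratios ----------------------------------------------
  mark_tab <- do.call(rbind, lapply(c("coding", "PROMPT"), function(cl) {
    gr <- classes[[cl]]
    win <- class_window(gr, win_class[[cl]])
    conds <- names(chip)
    ip_m <- vapply(conds, function(cond)
      region_basecount(chip[[cond]]$ip, win, strand_mode = "both"),
      numeric(length(win)))
    in_m <- vapply(conds, function(cond)
      region_basecount(chip[[cond]]$input, win, strand_mode = "both"),
      numeric(length(win)))
    ipq <- ip_minus_input_quant(
      ip_m, in_m,
      vapply(conds, function(cond) chip[[cond]]$ip@library_size, numeric(1)),
      vapply(conds, function(cond) chip[[cond]]$input@library_size, numeric(1)),
      BiocGenerics::width(win))
    data.frame(condition = conds, class = cl,
               median_log2_ip_minus_input =
                 apply(ipq$log2_value, 2, stats::median),
               n_regions = nrow(ipq$value), n_imputed = colSums(ipq$imputed),
               stringsAsFactors = FALSE)
  }))

  # --- metagene ------------------------------------------------------------
  coding_gr <- classes$coding
  tss <- GenomicRanges::resize(coding_gr, width = 1L, fix = "start")
  meta <- list(
    tss_control = reference_point_profile(net$control, tss, 1000, 3000),
    tss_depleted = reference_point_profile(net$depleted, tss, 1000, 3000),
    body_depleted = scale_regions_profile(net$depleted, coding_gr,
                                          body_bins = 100,
                                          upstream_bp = 1000,
                                          downstream_bp = 1000))

  # --- RDIP ----------------------------------------------------------------
  sim_pk <- simulate_peaks_and_origins(ann, seed = base_seed + 51L)
  rdip_track <- coverage_track(sim_pk$reads, sl, stranded = TRUE,
                               label = "RDIP")
  peaks <- assign_peak_strand(sim_pk$rdip, rdip_track)
  peaks <- categorize_peaks(peaks, ann$genes)
  cat_len <- category_lengths(ann$genes, sum(as.numeric(sl)))
  dist_raw <- category_distribution(peaks)
  dist_norm <- category_distribution(peaks, cat_len, normalize_by_size = TRUE)
  so <- summit_overlap(peaks, sim_pk$gamma, window_bp = 500,
                       n_random = 100, seed = base_seed + 52L)

  # --- origins -------------------------------------------------------------
  org <- classify_origins(ann$origins, tus)
  org <- origin_signal(org, net$control, net$depleted)
  org <- flag_induced(org)
  org <- nearest_ncrna(org, ann$prompts, ann$ernas)
  ext <- define_extended_lncrna(net$depleted, net$control,
                                c(ann$prompts, ann$genes[
                                  S4Vectors::mcols(ann$genes)$biotype %in%
                                    c("lincRNA", "antisense")]),
                                min_signal = 1, max_gap = 500)
  keep <- S4Vectors::mcols(org)$is_intergenic &
    S4Vectors::mcols(org)$positive_any
  near <- org[keep & S4Vectors::mcols(org)$near_ncrna]
  ov_frac <- if (length(near) > 0)
    origin_lncrna_overlap(near, ext) else NA_real_

  summary <- list(
    n_genes = length(ann$genes),
    tu_set_sizes = c(nonoverlapping_coding = length(nonov$members),
                     intronless = length(intronless$members)),
    n_prompt_pairs = nrow(ppairs),
    n_lincrna_pairs_kept = sum(lpairs$kept),
    class_log2_fold_change = stats::setNames(class_fc$log2_fc,
                                             class_fc$class),
    median_cri = stats::median(cri$cri),
    mark_ratios = mark_tab,
    rdip_category_fractions = dist_raw,
    rdip_category_density = dist_norm,
    summit_overlap = so$observed,
    summit_overlap_null_mean = mean(so$null),
    n_origins = length(org),
    n_intergenic = sum(S4Vectors::mcols(org)$is_intergenic),
    n_positive = sum(keep),
    n_induced = sum(S4Vectors::mcols(org)$induced_2x[keep]),
    n_near_ncrna = length(near),
    origin_extended_lncrna_overlap = ov_frac)

  run <- structure(list(
    annotation = ann, tracks = list(net = net, rna = rna, chip = chip),
    tu_sets = list(nonoverlapping_coding = nonov, intronless = intronless),
    pairs = list(prompt_mrna = ppairs, mrna_lincrna = lpairs),
    quant = quant, fold_changes = wide, cri = cri, mark_ratios = mark_tab,
    metagene = meta,
    rdip = list(peaks = peaks, gamma = sim_pk$gamma, raw = dist_raw,
                normalized = dist_norm, summit_overlap = so),
    origins = org, extended_lncrna = ext,
    summary = summary,
    log = list(seed = base_seed, depths = depths,
               package_version = as.character(utils::packageVersion("nascentr")),
               elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))),
    class = "nascentr_run")
  if (!is.null(outdir)) write_run(run, outdir)
  run
}

#' Write a pipeline run to disk
#'
#' Emits the annotation (GTF + BEDs), the summary tables (TSV), the
#' origin report, categorized peaks and a machine-readable run log
#' (JSON).  File contents are deterministic given the configuration.
#'
#' @param run a `"nascentr_run"`.
#' @param outdir output directory.
#' @return Invisibly, `outdir`.
#' @export
write_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_annotation(run$annotation, file.path(outdir, "annotation"))
  wt <- function(df, name)
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  wt(run$quant, "region_quant.tsv")
  wt(run$fold_changes, "fold_changes.tsv")
  wt(run$cri, "cri.tsv")
  wt(run$mark_ratios, "mark_ratios.tsv")
  wt(origin_report(run$origins), "origin_report.tsv")
  wt(data.frame(category = names(run$rdip$raw),
                fraction = as.numeric(run$rdip$raw),
                density = as.numeric(run$rdip$normalized)),
     "rdip_categories.tsv")
  pk <- run$rdip$peaks
  bed <- GenomicRanges::granges(pk)
  S4Vectors::mcols(bed)$name <- as.character(S4Vectors::mcols(pk)$category)
  S4Vectors::mcols(bed)$score <- 0L
  rtracklayer::export(bed, file.path(outdir, "rdip_categorized.bed"),
                      format = "BED")
  ebed <- GenomicRanges::granges(run$extended_lncrna)
  S4Vectors::mcols(ebed)$name <- S4Vectors::mcols(run$extended_lncrna)$gene_id
  S4Vectors::mcols(ebed)$score <- 0L
  rtracklayer::export(ebed, file.path(outdir, "extended_lncrna.bed"),
                      format = "BED")
  s <- run$summary
  flat <- s[!vapply(s, is.data.frame, logical(1))]
  jsonlite::write_json(
    list(summary = flat, log = run$log),
    file.path(outdir, "run_log.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(outdir)
}

#' @export
print.nascentr_run <- function(x, ...) {
  s <- x$summary
  cat("nascentr pipeline run (seed", x$log$seed, ")\n")
  cat("  genes:", s$n_genes,
      "| PROMPT pairs:", s$n_prompt_pairs,
      "| lincRNA pairs kept:", s$n_lincrna_pairs_kept, "\n")
  cat("  median class log2 fold changes (depleted/control):\n")
  print(round(s$class_log2_fold_change, 3))
  cat("  median CRI:", round(s$median_cri, 3), "\n")
  cat("  RDIP category fractions:\n")
  print(round(s$rdip_category_fractions, 3))
  cat("  summit overlap:", round(s$summit_overlap, 3),
      "(null mean", round(s$summit_overlap_null_mean, 3), ")\n")
  cat("  origins:", s$n_origins, "| intergenic:", s$n_intergenic,
      "| Pol II positive:", s$n_positive,
      "| 2-fold induced:", s$n_induced, "\n")
  invisible(x)
}
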