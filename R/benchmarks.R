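#' Ground-truth validation benchmarks
#'
#' Each benchmark builds a synthetic data set with a known planted
#' signal, runs the relevant pipeline stages on it, and reports the
#' recovered quantity next to the planted one.  They are the package's
#' reproducible validation studies: the test suite asserts on their
#' output and `scripts/acceptance.R` reports it.
#'
#' @name benchmarks
NULL

#' Fold-change recovery benchmark
#'
#' A genome in which protein-coding transcription dominates the library
#' (as it does genome-wide) and the lncRNA classes carry planted
#' depletion-condition induction folds: PROMPTs 4x, eRNAs 8x,
#' lincRNAs 2x.  Library depth is set so the least-expressed assessed
#' region class receives the requested expected read count per region in
#' the control library.  Recovery is the per-class median of
#' log2(depleted / control) normalized values over the class
#' quantification windows.  Because both libraries are sequenced to the
#' same total depth, global induction leaves a small negative
#' composition offset on every ratio; keeping the induced classes a
#' small fraction of the library bounds it well inside the assessment
#' tolerance.
#'
#' @param seed integer seed.
#' @param depth_per_region target expected control reads per assessed
#'   region.
#' @return A list: `recovered` and `planted` (named log2 fold changes),
#'   `depth` (library pairs), `n_regions` per class.
#' @export
fold_recovery_benchmark <- function(seed = 1L, depth_per_region = 1e4) {
  cfg <- sim_config(seed = seed, n_coding = 40L, n_lincrna = 4L,
                    n_prompt = 4L, n_erna = 4L,
                    rate_prompt = 0.5, rate_erna = 0.25,
                    rate_lincrna = 0.2, rate_origin = 0.02,
                    prompt_fold = 4, erna_fold = 8, lincrna_fold = 2)
  ann <- make_annotation(cfg)
  w <- ann$truth$weight
  share <- min(w[ann$truth$class %in% c("PROMPT", "eRNA")] / sum(w))
  depth <- ceiling(depth_per_region / share)
  net <- lapply(c(control = 11L, depleted = 12L), function(off) {
    p <- filter_proper_pairs(simulate_netseq(
      ann, if (off == 11L) "control" else "depleted", depth,
      seed = seed + off))
    extract_net_3prime(p, ann$seqlengths)
  })
  rec <- function(gr, cls) {
    win <- class_window(gr, cls)
    v <- lapply(net, function(tr) {
      normalize_quant(region_basecount(tr, win, "region"),
                      tr@library_size, BiocGenerics::width(win))$value
    })
    stats::median(log2(v$depleted / v$control))
  }
  linc <- ann$genes[S4Vectors::mcols(ann$genes)$biotype %in%
                      c("lincRNA", "antisense")]
  list(
    recovered = c(PROMPT = rec(ann$prompts, "PROMPT"),
                  eRNA = rec(ann$ernas, "eRNA"),
                  lincRNA = rec(linc, "lincRNA")),
    planted = c(PROMPT = log2(cfg$prompt_fold), eRNA = log2(cfg$erna_fold),
                lincRNA = log2(cfg$lincrna_fold)),
    depth = depth,
    n_regions = c(PROMPT = length(ann$prompts), eRNA = length(ann$ernas),
                  lincRNA = length(linc)))
}

#' Chromatin-retention recovery benchmark
#'
#' Chromatin and nucleoplasmic RNA-seq libraries simulated with a
#' planted PROMPT retention ratio; reports the median Chromatin
#' Retention Index over PROMPTs, which should equal log2 of the planted
#' ratio.
#'
#' @param seed integer seed.
#' @param retention planted chromatin:nucleoplasm ratio on PROMPTs.
#' @param depth pairs per fraction library.
#' @return A list: `median_cri`, `planted_log2`, `n_prompts`.
#' @export
cri_benchmark <- function(seed = 1L, retention = 2, depth = 2e6) {
  cfg <- sim_config(seed = seed, retention_prompt = retention)
  ann <- make_annotation(cfg)
  tracks <- lapply(c(chromatin = 21L, nucleoplasm = 22L), function(off) {
    p <- filter_proper_pairs(simulate_fraction_rnaseq(
      ann, if (off == 21L) "chromatin" else "nucleoplasm", depth,
      seed = seed + off))
    coverage_track(p, ann$seqlengths, stranded = TRUE)
  })
  win <- class_window(ann$prompts, "CRI_PROMPT")
  v <- lapply(tracks, function(tr)
    region_basecount(tr, win, "region") *
      (1e8 / tr@library_size) / BiocGenerics::width(win))
  cri <- chromatin_retention_index(
    v$chromatin, v$nucleoplasm,
    region_id = S4Vectors::mcols(ann$prompts)$gene_id)
  list(median_cri = stats::median(cri$cri),
       planted_log2 = log2(retention), n_prompts = length(ann$prompts))
}

#' Replication-origin induction benchmark
#'
#' The default genome plants 40 (intergenic) origins whose Pol II rate
#' quadruples upon depletion and 60 whose rate is flat; nascent libraries
#' are simulated so each origin window expects `coverage_per_origin`
#' control reads.  Induction flagging is assessed on the intergenic
#' analysis set, mirroring the collision analysis, which discards genic
#' origins because gene-body Pol II signal swamps the window.
#'
#' @param seed integer seed.
#' @param coverage_per_origin expected control reads per origin window.
#' @return A list: `n_induced_true`, `n_induced_flagged`,
#'   `n_false_positive`, `n_intergenic`, `n_genic`, `n_total`.
#' @export
origin_benchmark <- function(seed = 1L, coverage_per_origin = 20) {
  cfg <- sim_config(seed = seed)
  ann <- make_annotation(cfg)
  t <- ann$truth
  share <- min(t$weight[t$class == "origin"] / sum(t$weight))
  depth <- ceiling(coverage_per_origin / share)
  net <- lapply(c(control = 11L, depleted = 12L), function(off) {
    p <- filter_proper_pairs(simulate_netseq(
      ann, if (off == 11L) "control" else "depleted", depth,
      seed = seed + off))
    extract_net_3prime(p, ann$seqlengths)
  })
  org <- classify_origins(ann$origins, c(ann$genes, ann$prompts))
  org <- origin_signal(org, net$control, net$depleted)
  org <- flag_induced(org, fold = 2.0)
  mc <- S4Vectors::mcols(org)
  inter <- mc$is_intergenic
  list(n_induced_true = sum(mc$planted_induced),
       n_induced_flagged = sum(mc$induced_2x & mc$planted_induced & inter),
       n_false_positive = sum(mc$induced_2x & !mc$planted_induced & inter),
       n_intergenic = sum(inter),
       n_genic = sum(!inter),
       n_total = length(org))
}

#' R-loop / DNA-damage summit co-location benchmark
#'
#' Plants damage peaks at 80% of R-loop summits and measures the
#' recovered co-location fraction within a 500-bp window against the
#' random-placement null.  Peaks are laid out in distal (gene-free)
#' space, where planted co-location is identifiable: in the compact
#' exonic space of the toy genome, peak crowding would add chance
#' co-locations on top of the planted fraction.
#'
#' @param seed integer seed.
#' @param window_bp co-location window.
#' @param n_random random repositionings for the null.
#' @return A list: `observed`, `planted`, `null_mean`, `p_value`.
#' @export
colocation_benchmark <- function(seed = 1L, window_bp = 500,
                                 n_random = 100) {
  cfg <- sim_config(seed = seed, rdip_category_props = c(distal = 1))
  ann <- make_annotation(cfg)
  pk <- simulate_peaks_and_origins(ann, seed = seed + 51L)
  so <- summit_overlap(pk$rdip, pk$gamma, window_bp = window_bp,
                       n_random = n_random, seed = seed + 52L)
  list(observed = so$observed, planted = cfg$gamma_fraction,
       null_mean = mean(so$null), p_value = so$p_value)
}

#' Peak category recovery benchmark
#'
#' Plants `n_peaks` R-loop peaks with category proportions
#' 0.5 exon / 0.3 intron / 0.2 distal, categorizes them from the
#' annotation alone, and reports the recovered distribution.
#'
#' @param seed integer seed.
#' @param n_peaks number of planted peaks.
#' @return A list: `fractions` (recovered), `planted`, `strand_accuracy`
#'   (fraction of peaks whose strand is recovered from 20x strand-specific
#'   reads).
#' @export
category_benchmark <- function(seed = 1L, n_peaks = 1000L) {
  cfg <- sim_config(seed = seed, n_rdip_peaks = as.integer(n_peaks))
  ann <- make_annotation(cfg)
  pk <- simulate_peaks_and_origins(ann, seed = seed + 51L)
  track <- coverage_track(filter_proper_pairs(pk$reads), ann$seqlengths,
                          stranded = TRUE)
  peaks <- assign_peak_strand(pk$rdip, track)
  peaks <- categorize_peaks(peaks, ann$genes)
  mc <- S4Vectors::mcols(peaks)
  frac <- category_distribution(peaks)
  planted <- rep(0, length(frac)); names(planted) <- names(frac)
  pl <- table(mc$planted_category) / length(peaks)
  planted[names(pl)] <- as.numeric(pl)
  list(fractions = frac, planted = planted,
       strand_accuracy = mean(as.character(BiocGenerics::strand(peaks)) ==
                                mc$planted_strand))
}
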