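#' Simulation configuration
#'
#' Parameters of the synthetic genome and libraries used to validate the
#' pipeline against known ground truth.  The defaults describe a compact
#' three-chromosome toy genome whose signal structure mirrors the assays
#' the pipeline consumes: class-specific expression rates, a
#' depletion-condition induction of lncRNA classes, a 5'-to-3'
#' exponential signal decay on coding genes in the depleted condition (an
#' elongation defect), IP-over-input enrichment folds per chromatin mark,
#' a chromatin-vs-nucleoplasm retention ratio on PROMPTs, and
#' replication origins of which a fixed fraction gains Pol II signal upon
#' depletion.
#'
#' Expression weights are `rate x region length / 1 kb`; library reads
#' are multinomial over regions, so every library has exactly the
#' configured depth.
#'
#' @param seed integer; master seed for the genome layout.
#' @param n_chrom,chrom_length genome shape.
#' @param n_coding,n_intronless,n_histone,n_lincrna,n_snrna,n_prompt,n_erna,n_origins
#'   region counts per class (`n_prompt` coding genes host a divergent
#'   PROMPT; half the lincRNAs are divergent antisense partners of coding
#'   genes).
#' @param rate_coding,rate_intronless,rate_histone,rate_lincrna,rate_snrna,rate_prompt,rate_erna,rate_origin
#'   per-kb expression rates per class.
#' @param prompt_fold,erna_fold,lincrna_fold depletion-condition induction
#'   folds on the lncRNA classes.
#' @param coding_decay_bp decay length (bp) of the exponential 5'-to-3'
#'   coding-gene signal decay in the depleted condition.
#' @param prompt_extension_bp when > 0, depleted-condition PROMPT reads
#'   spread over `[TSS, TSS + extension]` instead of the annotated 1 kb,
#'   emulating depletion-induced transcriptional readthrough.
#' @param retention_prompt chromatin:nucleoplasm retention ratio planted
#'   on PROMPTs (all other classes partition 1:1).
#' @param ip_enrichment named list per mark; each entry has `control` and
#'   `depleted` named vectors of per-class IP/input enrichment folds
#'   (classes absent default to 1).
#' @param origin_induced_frac,origin_induced_fold fraction of origins
#'   whose Pol II rate is multiplied by the fold upon depletion.
#' @param origin_intergenic_frac fraction of origins placed in intergenic
#'   space.
#' @param n_rdip_peaks,rdip_category_props,rdip_peak_width,rdip_depth_per_peak
#'   R-loop peak count, planted genomic-category proportions, peak width,
#'   and strand-specific reads per peak.
#' @param gamma_fraction fraction of R-loop summits that receive a
#'   co-located DNA-damage peak (within 50 bp).
#' @param frag_len,read_len fragment and read lengths (bp).
#' @param gap_bp minimum spacing between placed features (bp).
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L, n_chrom = 3L, chrom_length = 2e6,
                       n_coding = 30L, n_intronless = 8L, n_histone = 4L,
                       n_lincrna = 10L, n_snrna = 8L, n_prompt = 20L,
                       n_erna = 20L, n_origins = 100L,
                       rate_coding = 1, rate_intronless = 0.8,
                       rate_histone = 1, rate_lincrna = 0.1,
                       rate_snrna = 2, rate_prompt = 0.05,
                       rate_erna = 0.05, rate_origin = 0.2,
                       prompt_fold = 4, erna_fold = 4, lincrna_fold = 2,
                       coding_decay_bp = 2000, prompt_extension_bp = 0,
                       retention_prompt = 2,
                       ip_enrichment = list(H3K36me3 = list(
                         control = c(coding = 8, intronless = 8, histone = 8,
                                     lincRNA = 2, PROMPT = 1),
                         depleted = c(coding = 2, intronless = 2, histone = 2,
                                      lincRNA = 2, PROMPT = 4))),
                       origin_induced_frac = 0.4, origin_induced_fold = 4,
                       origin_intergenic_frac = 0.8,
                       n_rdip_peaks = 400L,
                       rdip_category_props = c(exon = 0.5, intron = 0.3,
                                               distal = 0.2),
                       rdip_peak_width = 300L, rdip_depth_per_peak = 20L,
                       gamma_fraction = 0.8,
                       frag_len = 150L, read_len = 75L, gap_bp = 6000L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_prompt <= cfg$n_coding,
            all(unlist(cfg[grep("^rate_", names(cfg))]) >= 0),
            abs(sum(rdip_category_props) - 1) < 1e-8)
  structure(cfg, class = "sim_config")
}

sim_seqlengths <- function(config) {
  stats::setNames(rep(as.integer(config$chrom_length), config$n_chrom),
                  paste0("chr", seq_len(config$n_chrom)))
}

#' Build the synthetic annotation and ground truth
#'
#' Lays out all region classes without overlap: each coding gene may host
#' a divergent PROMPT or antisense lincRNA on the opposite strand just
#' upstream of its TSS; eRNA centers, snRNA genes and intergenic
#' replication origins occupy the gaps; a fraction of origins is placed
#' inside coding-gene bodies.  The ground-truth table records, for every
#' region, its class, planted expression weight per condition, retention
#' ratio and (for origins) the planted induced/intergenic flags.
#'
#' @param config a [sim_config()].
#' @return A list of class `"sim_annotation"`: `genes` (TU `GRanges` with
#'   exons, GTF classes only), `prompts`, `ernas`, `origins` (`GRanges`),
#'   `truth` (data frame), `seqlengths`, `config`.
#' @export
make_annotation <- function(config = sim_config()) {
  sl <- sim_seqlengths(config)
  with_seed(config$seed, build_annotation(config, sl))
}

build_annotation <- function(cfg, sl) {
  cursor <- stats::setNames(rep(10000L, cfg$n_chrom), names(sl))
  chrom_of <- function(i) names(sl)[((i - 1L) %% cfg$n_chrom) + 1L]
  rows <- list(); exon_list <- list()
  unit_i <- 0L

  place <- function(chrom, footprint) {
    # returns start of the footprint; advances the cursor
    gap <- cfg$gap_bp + sample.int(2000L, 1L)
    st <- cursor[[chrom]] + gap
    if (st + footprint > sl[[chrom]] - 10000L)
      stop("infeasible packing: genome too small for the requested ",
           "region counts; increase chrom_length")
    cursor[[chrom]] <<- st + footprint
    st
  }
  add <- function(id, class, chrom, start, end, strand, rate, fold = 1,
                  retention = 1, exons = NULL, name = id,
                  sim_start = start, sim_end = end) {
    unit_i <<- unit_i + 1L
    rows[[unit_i]] <<- data.frame(
      region_id = id, class = class, name = name, chrom = chrom,
      start = start, end = end, strand = strand,
      weight = rate * (end - start + 1) / 1000,
      fold_depleted = fold, retention = retention,
      sim_start = sim_start, sim_end = sim_end,
      stringsAsFactors = FALSE)
    if (!is.null(exons)) exon_list[[id]] <<- exons
  }

  n_div_linc <- cfg$n_lincrna %/% 2L
  # coding genes, possibly with a divergent partner upstream of the TSS
  for (i in seq_len(cfg$n_coding)) {
    chrom <- chrom_of(i)
    strand <- if (i %% 2L == 1L) "+" else "-"
    n_ex <- sample(2:5, 1L)
    ex_w <- sample(200:600, n_ex, replace = TRUE)
    in_w <- if (n_ex > 1L) sample(800:4000, n_ex - 1L, replace = TRUE) else integer()
    w <- sum(ex_w) + sum(in_w)
    partner <- if (i <= cfg$n_prompt) "PROMPT"
      else if (i <= cfg$n_prompt + n_div_linc) "antisense" else "none"
    pl <- switch(partner, PROMPT = 1000L, antisense = sample(2000:5000, 1L), none = 0L)
    off <- if (partner == "none") 0L else
      if (partner == "PROMPT") sample(50:500, 1L) else sample(500:2500, 1L)
    st <- place(chrom, w + pl + off)
    if (strand == "+") {
      g_st <- st + pl + off; g_en <- g_st + w - 1L
      p_st <- st; p_en <- st + pl - 1L; p_strand <- "-"
    } else {
      g_st <- st; g_en <- st + w - 1L
      p_st <- g_en + off + 1L; p_en <- p_st + pl - 1L; p_strand <- "+"
    }
    # exon layout 5'->3'
    seg <- as.vector(rbind(ex_w, c(in_w, 0L)))[seq_len(2L * n_ex - 1L)]
    bounds <- cumsum(c(0L, seg))
    ex_idx <- seq(1L, 2L * n_ex - 1L, by = 2L)
    if (strand == "+") {
      ex_s <- g_st + bounds[ex_idx]; ex_e <- g_st + bounds[ex_idx + 1L] - 1L
    } else {
      ex_e <- g_en - bounds[ex_idx]; ex_s <- g_en - bounds[ex_idx + 1L] + 1L
    }
    gid <- sprintf("GCOD%02d", i)
    add(gid, "coding", chrom, g_st, g_en, strand, cfg$rate_coding,
        exons = IRanges::IRanges(sort(ex_s), sort(ex_e)), name = gid)
    if (partner == "PROMPT") {
      pid <- sprintf("PROMPT%02d", i)
      add(pid, "PROMPT", chrom, p_st, p_en, p_strand, cfg$rate_prompt,
          fold = cfg$prompt_fold, retention = cfg$retention_prompt,
          exons = IRanges::IRanges(p_st, p_en), name = pid)
    } else if (partner == "antisense") {
      lid <- sprintf("LINCD%02d", i)
      add(lid, "antisense", chrom, p_st, p_en, p_strand, cfg$rate_lincrna,
          fold = cfg$lincrna_fold,
          exons = IRanges::IRanges(p_st, p_en), name = lid)
    }
  }
  standalone <- function(n, class, prefix, len_range, rate, fold = 1,
                         strand_choice = c("+", "-"), exonize = TRUE) {
    for (i in seq_len(n)) {
      chrom <- chrom_of(i)
      w <- if (length(len_range) == 1L) len_range
           else sample(len_range[1]:len_range[2], 1L)
      st <- place(chrom, w)
      strand <- sample(strand_choice, 1L)
      id <- sprintf("%s%02d", prefix, i)
      add(id, class, chrom, st, st + w - 1L, strand, rate, fold = fold,
          exons = if (exonize) IRanges::IRanges(st, st + w - 1L))
    }
  }
  standalone(cfg$n_intronless, "intronless", "INTL", c(1500L, 4000L),
             cfg$rate_intronless)
  standalone(cfg$n_histone, "histone", "HIST1H2B", c(400L, 800L),
             cfg$rate_histone)
  standalone(cfg$n_lincrna - n_div_linc, "lincRNA", "LINC", c(2000L, 5000L),
             cfg$rate_lincrna, fold = cfg$lincrna_fold)
  standalone(cfg$n_snrna, "snRNA", "SNRNA", c(120L, 250L), cfg$rate_snrna)
  # eRNA: 400-bp unstranded centers; reads spread over center +/- 1 kb
  for (i in seq_len(cfg$n_erna)) {
    chrom <- chrom_of(i)
    st <- place(chrom, 2000L)
    mid <- st + 1000L
    add(sprintf("ERNA%02d", i), "eRNA", chrom, mid - 200L, mid + 199L, "*",
        0, fold = cfg$erna_fold, sim_start = mid - 1000L, sim_end = mid + 999L)
    rows[[unit_i]]$weight <- cfg$rate_erna * 2   # rate x 2 kb sim span
  }
  # origins: intergenic ones are placed in the layout, genic ones inside
  # coding-gene bodies.  Induction is planted on intergenic origins only:
  # genic windows sit on gene-body Pol II signal that dwarfs their own,
  # which is why the collision analysis restricts itself to intergenic
  # origins in the first place.
  n_inter <- round(cfg$origin_intergenic_frac * cfg$n_origins)
  n_ind <- round(cfg$origin_induced_frac * cfg$n_origins)
  if (n_ind > n_inter)
    stop("origin_induced_frac exceeds the intergenic origin count")
  induced <- rep(FALSE, cfg$n_origins)
  induced[sample.int(n_inter, n_ind)] <- TRUE
  coding_rows <- which(vapply(rows, function(r) r$class == "coding", logical(1)))
  for (i in seq_len(cfg$n_origins)) {
    id <- sprintf("ORI%03d", i)
    fold <- if (induced[i]) cfg$origin_induced_fold else 1
    if (i <= n_inter) {
      chrom <- chrom_of(i)
      st <- place(chrom, 1000L)
      add(id, "origin", chrom, st, st + 999L, "*", cfg$rate_origin, fold = fold)
    } else {
      host <- rows[[sample(coding_rows, 1L)]]
      st <- host$start + sample.int(host$end - host$start - 1000L, 1L)
      add(id, "origin", host$chrom, st, st + 999L, "*", cfg$rate_origin,
          fold = fold)
    }
    rows[[unit_i]]$origin_intergenic <- i <= n_inter
    rows[[unit_i]]$origin_induced <- induced[i]
  }
  truth <- do.call(rbind, lapply(rows, function(r) {
    if (is.null(r$origin_intergenic)) {
      r$origin_intergenic <- NA; r$origin_induced <- NA
    }
    r
  }))

  as_gr <- function(df, with_exons = FALSE) {
    gr <- GenomicRanges::GRanges(
      df$chrom, IRanges::IRanges(df$start, df$end), strand = df$strand,
      gene_id = df$region_id, gene_name = df$name, biotype = df$class,
      seqlengths = sim_seqlengths(cfg))
    mc <- S4Vectors::mcols(gr)
    mc$tss <- ifelse(df$strand == "-", df$end, df$start)
    mc$tes <- ifelse(df$strand == "-", df$start, df$end)
    if (with_exons) {
      exl <- IRanges::IRangesList(exon_list[df$region_id])
      mc$n_exons <- lengths(exl)
      mc$exons <- exl
    }
    S4Vectors::mcols(gr) <- mc
    gr
  }
  gene_classes <- c("coding", "intronless", "histone", "lincRNA",
                    "antisense", "snRNA")
  genes <- as_gr(truth[truth$class %in% gene_classes, ], with_exons = TRUE)
  mc <- S4Vectors::mcols(genes)
  mc$biotype <- unname(c(coding = "protein_coding",
                         intronless = "protein_coding",
                         histone = "histone", lincRNA = "lincRNA",
                         antisense = "antisense", snRNA = "snRNA")[mc$biotype])
  S4Vectors::mcols(genes) <- mc
  origins_df <- truth[truth$class == "origin", ]
  origins <- GenomicRanges::GRanges(
    origins_df$chrom, IRanges::IRanges(origins_df$start, origins_df$end),
    origin_id = origins_df$region_id,
    planted_intergenic = origins_df$origin_intergenic,
    planted_induced = origins_df$origin_induced,
    seqlengths = sim_seqlengths(cfg))
  structure(list(genes = BiocGenerics::sort(genes),
                 prompts = BiocGenerics::sort(as_gr(truth[truth$class == "PROMPT", ],
                                                    with_exons = TRUE)),
                 ernas = BiocGenerics::sort(as_gr(truth[truth$class == "eRNA", ])),
                 origins = BiocGenerics::sort(origins),
                 truth = truth, seqlengths = sim_seqlengths(cfg),
                 config = cfg),
            class = "sim_annotation")
}

sim_weights <- function(ann, condition) {
  t <- ann$truth
  w <- t$weight
  if (condition == "depleted") w <- w * t$fold_depleted
  w
}

#' Simulate a nascent-transcription (mNET-seq style) library
#'
#' Draws exactly `depth` read pairs, multinomially over regions with
#' weight `rate x length x condition fold`.  Each pair's read-2 3' end is
#' the simulated nascent position: uniform within the region, except
#' coding genes in the depleted condition, whose positions decay
#' exponentially from the TSS (the elongation defect), and PROMPTs under
#' a configured readthrough extension.  Pair geometry follows the
#' `reverse_of_read1` library convention.
#'
#' @param ann a [make_annotation()] result.
#' @param condition `"control"` or `"depleted"`.
#' @param depth total read pairs (> 0).
#' @param seed RNG seed.
#' @return An [aligned_pairs()] data frame of exactly `depth` rows.
#' @export
simulate_netseq <- function(ann, condition = c("control", "depleted"),
                            depth, seed = 1L) {
  condition <- match.arg(condition)
  if (depth <= 0) stop("depth must be > 0")
  cfg <- ann$config
  t <- ann$truth
  w <- sim_weights(ann, condition)
  with_seed(seed, {
    cnt <- stats::rmultinom(1, depth, w)[, 1]
    pos <- vector("list", nrow(t)); strd <- vector("list", nrow(t))
    for (i in which(cnt > 0)) {
      n <- cnt[i]
      s0 <- t$sim_start[i]; e0 <- t$sim_end[i]
      if (t$class[i] == "coding" && condition == "depleted") {
        wd <- e0 - s0 + 1L
        lam <- cfg$coding_decay_bp
        u <- stats::runif(n)
        d <- floor(-lam * log(1 - u * (1 - exp(-wd / lam))))  # truncated exp
        p <- if (t$strand[i] == "+") s0 + d else e0 - d
      } else if (t$class[i] == "PROMPT" && condition == "depleted" &&
                 cfg$prompt_extension_bp > 0) {
        ext <- cfg$prompt_extension_bp
        if (t$strand[i] == "-") {
          tss <- e0
          p <- tss - sample.int(ext, n, replace = TRUE) + 1L
        } else {
          tss <- s0
          p <- tss + sample.int(ext, n, replace = TRUE) - 1L
        }
        p <- pmin(pmax(p, 1L), ann$seqlengths[[t$chrom[i]]])
      } else {
        p <- s0 + sample.int(e0 - s0 + 1L, n, replace = TRUE) - 1L
      }
      pos[[i]] <- p
      strd[[i]] <- if (t$strand[i] == "*")
        sample(c("+", "-"), n, replace = TRUE) else rep(t$strand[i], n)
    }
    idx <- rep(seq_len(nrow(t)), cnt)
    build_net_pairs(t$chrom[idx], unlist(pos), unlist(strd),
                    ann$seqlengths, cfg, condition)
  })
}

# 3'-end positions -> proper pairs under the reverse_of_read1 convention
build_net_pairs <- function(chrom, pos, sig_strand, sl, cfg, label) {
  rl <- cfg$read_len; fl <- cfg$frag_len
  n <- length(pos)
  pos <- as.integer(pos)
  plus <- sig_strand == "+"
  L <- unname(sl[chrom])
  r2_start <- pos; r2_end <- pmin.int(L, pos + rl - 1L)
  r2_start[plus] <- pmax.int(1L, pos[plus] - rl + 1L)
  r2_end[plus] <- pos[plus]
  r1_start <- pmax.int(1L, pos + fl - rl)
  r1_start[plus] <- pmax.int(1L, pos[plus] - fl + 1L)
  r1_end <- pmin.int(L, r1_start + rl - 1L)
  r1_strand <- rep("-", n); r1_strand[!plus] <- "+"
  aligned_pairs(
    qname = rep(label, n),
    chrom = chrom,
    r1_start = r1_start, r1_end = r1_end,
    r1_strand = r1_strand,
    r2_start = r2_start, r2_end = r2_end, r2_strand = sig_strand)
}

#' Simulate a subcellular-fraction RNA-seq library
#'
#' Fragment-coverage reads over the annotated regions.  Chromatin
#' libraries weight each region by its planted retention ratio;
#' nucleoplasmic libraries use the base weights, so the planted
#' chromatin:nucleoplasm signal ratio per region equals its retention
#' ratio.
#'
#' @param ann a [make_annotation()] result.
#' @param fraction `"chromatin"` or `"nucleoplasm"`.
#' @param depth total read pairs.
#' @param seed RNG seed.
#' @return An [aligned_pairs()] data frame.
#' @export
simulate_fraction_rnaseq <- function(ann,
                                     fraction = c("chromatin", "nucleoplasm"),
                                     depth, seed = 1L) {
  fraction <- match.arg(fraction)
  if (depth <= 0) stop("depth must be > 0")
  cfg <- ann$config
  t <- ann$truth
  keep <- t$class != "origin"
  w <- t$weight * if (fraction == "chromatin") t$retention else 1
  w[!keep] <- 0
  with_seed(seed, {
    cnt <- stats::rmultinom(1, depth, w)[, 1]
    idx <- rep(seq_len(nrow(t)), cnt)
    width <- t$sim_end[idx] - t$sim_start[idx] + 1L
    fstart <- t$sim_start[idx] +
      floor(stats::runif(length(idx)) * pmax(1L, width - cfg$frag_len))
    strd <- ifelse(t$strand[idx] == "*",
                   sample(c("+", "-"), length(idx), replace = TRUE),
                   t$strand[idx])
    build_fragment_pairs(t$chrom[idx], fstart, strd, ann$seqlengths, cfg,
                         fraction)
  })
}

build_fragment_pairs <- function(chrom, fstart, sig_strand, sl, cfg, label) {
  rl <- cfg$read_len; fl <- cfg$frag_len
  fstart <- pmax.int(1L, as.integer(fstart))
  fend <- pmin.int(unname(sl[chrom]), fstart + fl - 1L)
  n <- length(fstart)
  plus <- sig_strand == "+"
  five <- pmin.int(fend, fstart + rl - 1L)   # fragment 5'-side read span end
  three <- pmax.int(1L, fend - rl + 1L)      # fragment 3'-side read start
  # read1 maps antisense to the transcript (dUTP first-strand), read2 sense
  r2_start <- three; r2_end <- fend
  r2_start[plus] <- fstart[plus]; r2_end[plus] <- five[plus]
  r1_start <- fstart; r1_end <- five
  r1_start[plus] <- three[plus]; r1_end[plus] <- fend[plus]
  r1_strand <- rep("-", n); r1_strand[!plus] <- "+"
  aligned_pairs(
    qname = rep(label, n),
    chrom = chrom,
    r1_start = r1_start, r1_end = r1_end,
    r1_strand = r1_strand,
    r2_start = r2_start, r2_end = r2_end, r2_strand = sig_strand)
}

#' Simulate an IP + input chromatin-mark library pair
#'
#' The input library is uniform over the genome; the IP library overlays
#' region-specific extra mass so the planted IP:input density ratio over
#' a region equals the configured per-class enrichment fold for the mark
#' and condition.  Both libraries are unstranded fragment coverage.
#'
#' @param ann a [make_annotation()] result.
#' @param mark mark name (a key of `config$ip_enrichment`).
#' @param condition `"control"` or `"depleted"`.
#' @param depth pairs per library.
#' @param seed RNG seed.
#' @param dup_fraction fraction of pairs flagged as PCR duplicates in each
#'   library.
#' @return A list: `ip`, `input` ([aligned_pairs()]).
#' @export
simulate_ip_input <- function(ann, mark = "H3K36me3",
                              condition = c("control", "depleted"),
                              depth, seed = 1L, dup_fraction = 0) {
  condition <- match.arg(condition)
  cfg <- ann$config
  enr_tab <- cfg$ip_enrichment[[mark]]
  if (is.null(enr_tab)) stop("no enrichment configured for mark ", mark)
  enr <- enr_tab[[condition]]
  t <- ann$truth
  sl <- ann$seqlengths
  genic <- t$class != "origin"
  fold <- ifelse(is.na(enr[t$class]), 1, enr[t$class])
  fold[!genic] <- 1
  with_seed(seed, {
    sim_lib <- function(region_extra, label) {
      w_bg <- as.numeric(sl) / 1000           # uniform background per chrom
      w_rg <- (t$end - t$start + 1) / 1000 * region_extra
      w <- c(w_bg, w_rg)
      cnt <- stats::rmultinom(1, depth, w)[, 1]
      nb <- length(sl)
      bg_idx <- rep(seq_len(nb), cnt[seq_len(nb)])
      bg_pos <- floor(stats::runif(length(bg_idx)) *
                        (as.numeric(sl)[bg_idx] - cfg$frag_len)) + 1L
      rg_cnt <- cnt[-seq_len(nb)]
      rg_idx <- rep(seq_len(nrow(t)), rg_cnt)
      rg_pos <- t$start[rg_idx] +
        floor(stats::runif(length(rg_idx)) *
                pmax(1L, t$end[rg_idx] - t$start[rg_idx] + 1L - cfg$frag_len))
      chrom <- c(names(sl)[bg_idx], t$chrom[rg_idx])
      fstart <- c(bg_pos, rg_pos)
      strd <- sample(c("+", "-"), length(fstart), replace = TRUE)
      p <- build_fragment_pairs(chrom, fstart, strd, sl, cfg, label)
      if (dup_fraction > 0) {
        ndup <- floor(dup_fraction * nrow(p))
        p$duplicate[sample.int(nrow(p), ndup)] <- TRUE
      }
      p
    }
    list(ip = sim_lib(fold - 1, paste0(mark, "_ip")),
         input = sim_lib(0, paste0(mark, "_input")))
  })
}

#' Simulate R-loop peaks, damage peaks and their reads
#'
#' Plants `n_rdip_peaks` R-loop peaks at positions realizing the
#' configured genomic-category proportions (summit in an exon, an intron,
#' a TSS/TES flank or distal space), with the host gene's strand (random
#' for distal).  A configured fraction of summits receives a co-located
#' DNA-damage peak within 50 bp; the remaining damage peaks are placed at
#' random distal positions.  Strand-specific reads (uniform within each
#' peak on its planted strand) drive strand assignment.
#'
#' @param ann a [make_annotation()] result.
#' @param seed RNG seed.
#' @return A list: `rdip` (peak `GRanges` with `summit`,
#'   `planted_category`, `planted_strand`), `gamma` (peak `GRanges` with
#'   `summit`), `reads` ([aligned_pairs()] of strand-specific RDIP
#'   reads).
#' @export
simulate_peaks_and_origins <- function(ann, seed = 1L) {
  cfg <- ann$config
  sl <- ann$seqlengths
  tus <- ann$genes
  half <- cfg$rdip_peak_width %/% 2L
  with_seed(seed, {
    exons <- tu_exon_granges(tus)
    introns <- GenomicRanges::setdiff(GenomicRanges::granges(tus), exons,
                                      ignore.strand = TRUE)
    up <- GenomicRanges::trim(GenomicRanges::flank(tus, 2000L, start = TRUE))
    dn <- GenomicRanges::trim(GenomicRanges::flank(tus, 2000L, start = FALSE))
    feat <- c(GenomicRanges::granges(tus), GenomicRanges::granges(ann$prompts),
              GenomicRanges::granges(ann$ernas))
    pad <- GenomicRanges::trim(GenomicRanges::resize(
      feat, width = BiocGenerics::width(feat) + 5000L, fix = "center"))
    distal <- GenomicRanges::gaps(IRanges::reduce(pad, ignore.strand = TRUE))
    distal <- distal[BiocGenerics::strand(distal) == "*" &
                       BiocGenerics::width(distal) > 2L * cfg$rdip_peak_width]

    host_strand <- function(pos_gr) {
      h <- GenomicRanges::nearest(pos_gr, tus, ignore.strand = TRUE)
      as.character(BiocGenerics::strand(tus))[h]
    }
    props <- cfg$rdip_category_props
    cats <- sample(names(props), cfg$n_rdip_peaks, replace = TRUE,
                   prob = props)
    pools <- list(exon = exons, intron = introns, upstream = up,
                  downstream = dn, distal = distal)
    summit <- integer(cfg$n_rdip_peaks)
    chrom <- character(cfg$n_rdip_peaks)
    for (cat in unique(cats)) {
      ii <- which(cats == cat)
      pool <- pools[[cat]]
      w <- BiocGenerics::width(pool) - 2L
      pi <- sample.int(length(pool), length(ii), replace = TRUE, prob = w)
      summit[ii] <- BiocGenerics::start(pool)[pi] + 1L +
        floor(stats::runif(length(ii)) * w[pi])
      chrom[ii] <- as.character(GenomeInfoDb::seqnames(pool))[pi]
    }
    pos_gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(summit, summit),
                                     seqlengths = sl)
    strd <- host_strand(pos_gr)
    strd[cats == "distal"] <- sample(c("+", "-"), sum(cats == "distal"),
                                     replace = TRUE)
    rdip <- GenomicRanges::GRanges(
      chrom,
      IRanges::IRanges(pmax(1L, summit - half),
                       pmin(sl[chrom], summit + half - 1L)),
      summit = summit,
      planted_category = cats, planted_strand = strd,
      score = round(stats::runif(cfg$n_rdip_peaks, 10, 1000)),
      seqlengths = sl)

    n_co <- round(cfg$gamma_fraction * cfg$n_rdip_peaks)
    co_idx <- sample.int(cfg$n_rdip_peaks, n_co)
    g_summit <- summit[co_idx] + sample(-50:50, n_co, replace = TRUE)
    g_chrom <- chrom[co_idx]
    n_far <- cfg$n_rdip_peaks - n_co
    if (n_far > 0) {
      ii <- sample.int(length(distal), n_far, replace = TRUE,
                       prob = BiocGenerics::width(distal) - 2L)
      far_chrom <- as.character(GenomeInfoDb::seqnames(distal))[ii]
      far_pos <- BiocGenerics::start(distal)[ii] + 1L +
        floor(stats::runif(n_far) * (BiocGenerics::width(distal)[ii] - 2L))
      g_summit <- c(g_summit, far_pos)
      g_chrom <- c(g_chrom, far_chrom)
    }
    gamma <- GenomicRanges::GRanges(
      g_chrom,
      IRanges::IRanges(pmax(1L, g_summit - half),
                       pmin(sl[g_chrom], g_summit + half - 1L)),
      summit = as.integer(g_summit), seqlengths = sl)

    # strand-specific reads over each peak at the configured coverage
    n_reads <- cfg$rdip_depth_per_peak
    idx <- rep(seq_len(cfg$n_rdip_peaks), each = n_reads)
    rpos <- BiocGenerics::start(rdip)[idx] +
      floor(stats::runif(length(idx)) *
              pmax(1L, BiocGenerics::width(rdip)[idx] - cfg$frag_len))
    reads <- build_fragment_pairs(chrom[idx], rpos, strd[idx], sl, cfg,
                                  "rdip")
    list(rdip = rdip, gamma = gamma, reads = reads)
  })
}

#' Write the synthetic annotation to standard formats
#'
#' Emits the gene models as GTF (gene/transcript/exon records with
#' `gene_id`, `transcript_id`, `gene_type`, `gene_name`), the PROMPT and
#' eRNA sets as 6-column BED, and the origin windows as BED.
#'
#' @param ann a [make_annotation()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_annotation <- function(ann, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genes <- ann$genes
  mc <- S4Vectors::mcols(genes)
  gtf_type <- c(protein_coding = "protein_coding", histone = "protein_coding",
                lincRNA = "lincRNA", antisense = "antisense",
                snRNA = "snRNA")[mc$biotype]
  recs <- list()
  for (i in seq_along(genes)) {
    ex <- mc$exons[[i]]
    n <- length(ex)
    chrom <- as.character(GenomeInfoDb::seqnames(genes))[i]
    strand <- as.character(BiocGenerics::strand(genes))[i]
    tid <- paste0(mc$gene_id[i], ".1")
    recs[[i]] <- GenomicRanges::GRanges(
      rep(chrom, n + 2L),
      c(IRanges::ranges(genes)[i], IRanges::ranges(genes)[i], ex),
      strand = strand,
      type = c("gene", "transcript", rep("exon", n)),
      gene_id = mc$gene_id[i],
      transcript_id = c(NA, rep(tid, n + 1L)),
      gene_type = gtf_type[i],
      gene_name = mc$gene_name[i])
  }
  gtf <- suppressWarnings(do.call(c, recs))
  GenomeInfoDb::seqlevels(gtf) <- names(ann$seqlengths)
  GenomeInfoDb::seqlengths(gtf) <- ann$seqlengths
  paths <- c(
    gtf = file.path(dir, "annotation.gtf"),
    prompts = file.path(dir, "prompts.bed"),
    ernas = file.path(dir, "ernas.bed"),
    origins = file.path(dir, "origins.bed"))
  rtracklayer::export(gtf, paths[["gtf"]], format = "gtf")
  bed6 <- function(gr, ids) {
    out <- GenomicRanges::granges(gr)
    S4Vectors::mcols(out)$name <- ids
    S4Vectors::mcols(out)$score <- 0L
    out
  }
  rtracklayer::export(bed6(ann$prompts, S4Vectors::mcols(ann$prompts)$gene_id),
                      paths[["prompts"]], format = "BED")
  rtracklayer::export(bed6(ann$ernas, S4Vectors::mcols(ann$ernas)$gene_id),
                      paths[["ernas"]], format = "BED")
  rtracklayer::export(bed6(ann$origins, S4Vectors::mcols(ann$origins)$origin_id),
                      paths[["origins"]], format = "BED")
  invisible(paths)
}
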