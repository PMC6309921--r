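gtf_fixture <- function(strand = "+") {
  # two transcripts [101,500] and [151,700]; exons cover the spans
  GenomicRanges::GRanges(
    "chrA",
    IRanges::IRanges(c(101, 101, 151, 151), c(700, 500, 500, 700)),
    strand = strand,
    type = c("gene", "exon", "exon", "exon"),
    gene_id = "gX",
    transcript_id = c(NA, "gX.1", "gX.1", "gX.2"),
    gene_type = "protein_coding",
    gene_name = "GX")
}

test_that("a TU spans the union of its transcripts, 5'-most TSS to 3'-most end", {
  tu <- extract_tus(gtf_fixture("+"))
  expect_equal(GenomicRanges::start(tu), 101)
  expect_equal(GenomicRanges::end(tu), 700)
  expect_equal(S4Vectors::mcols(tu)$tss, 101)
  expect_equal(S4Vectors::mcols(tu)$tes, 700)
  # same transcripts on -: interval unchanged, tss/tes mirror
  tu2 <- extract_tus(gtf_fixture("-"))
  expect_equal(GenomicRanges::start(tu2), 101)
  expect_equal(GenomicRanges::end(tu2), 700)
  expect_equal(S4Vectors::mcols(tu2)$tss, 700)
  expect_equal(S4Vectors::mcols(tu2)$tes, 101)
})

test_that("TU extraction matches per-gene brute-force min/max on a 3-gene fixture", {
  set.seed(21)
  recs <- list()
  truth <- list()
  for (g in 1:3) {
    n_tx <- sample(1:3, 1)
    st <- sample(1000:5000, n_tx) + g * 10000L
    en <- st + sample(500:3000, n_tx)
    strand <- sample(c("+", "-"), 1)
    truth[[g]] <- data.frame(gene = paste0("g", g), start = min(st),
                             end = max(en), strand = strand)
    recs[[g]] <- GenomicRanges::GRanges(
      "chrA", IRanges::IRanges(st, en), strand = strand,
      type = "exon", gene_id = paste0("g", g),
      transcript_id = paste0("g", g, ".", seq_len(n_tx)),
      gene_type = "protein_coding", gene_name = paste0("G", g))
  }
  tus <- extract_tus(suppressWarnings(do.call(c, recs)))
  tr <- do.call(rbind, truth)
  tr <- tr[match(S4Vectors::mcols(tus)$gene_id, tr$gene), ]
  expect_equal(GenomicRanges::start(tus), tr$start)
  expect_equal(GenomicRanges::end(tus), tr$end)
  expect_equal(S4Vectors::mcols(tus)$tss,
               ifelse(tr$strand == "+", tr$start, tr$end))
})

test_that("TU extraction round-trips through the generator's GTF", {
  ann <- make_annotation(sim_config(seed = 2, n_coding = 6L, n_prompt = 2L,
                                    n_lincrna = 4L, n_erna = 2L,
                                    n_origins = 10L))
  dir <- tempfile()
  paths <- write_annotation(ann, dir)
  tus <- extract_tus(paths[["gtf"]])
  ref <- ann$genes
  expect_equal(length(tus), length(ref))
  ord <- match(S4Vectors::mcols(ref)$gene_id, S4Vectors::mcols(tus)$gene_id)
  expect_equal(GenomicRanges::start(tus)[ord], GenomicRanges::start(ref))
  expect_equal(GenomicRanges::end(tus)[ord], GenomicRanges::end(ref))
  expect_equal(S4Vectors::mcols(tus)$biotype[ord],
               S4Vectors::mcols(ref)$biotype)
  expect_equal(S4Vectors::mcols(tus)$n_exons[ord],
               S4Vectors::mcols(ref)$n_exons)
})

make_tier_tus <- function(n_per_tier = 10, len = 10000L, spacing = 30000L) {
  n <- 4 * n_per_tier
  st <- seq_len(n) * spacing
  GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(st, st + len - 1L), strand = "+",
    gene_id = sprintf("t%02d", seq_len(n)),
    gene_name = sprintf("T%02d", seq_len(n)),
    biotype = "protein_coding",
    tss = st, tes = st + len - 1L, n_exons = 1L,
    seqlengths = c(chrT = 41L * spacing))
}

test_that("the four-tier expression fixture selects exactly the top three tiers", {
  tus <- make_tier_tus()
  tiers <- rep(c(0, 10, 100, 1000), each = 10)
  track <- track_from_regions(tus, tiers, seqlengths = c(chrT = 41L * 30000L))
  rep1 <- select_nonoverlapping_coding(tus, track, seed = 1L)
  expected <- S4Vectors::mcols(tus)$gene_id[tiers > 0]
  expect_setequal(rep1$members, expected)
  expect_equal(unname(rep1$provenance[["top_expression_groups"]]), 30L)
  # seed-invariant under wide tier separation
  for (s in 2:5)
    expect_setequal(select_nonoverlapping_coding(tus, track, seed = s)$members,
                    expected)
  # provenance is monotone non-increasing
  expect_true(all(diff(as.integer(rep1$provenance)) <= 0))
})

test_that("geometric filters exclude crowded and short genes", {
  tus <- make_tier_tus()
  # plant a neighbor ending 1 kb upstream of t01's TSS
  neighbor <- GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(GenomicRanges::start(tus)[1] - 3000L,
                             GenomicRanges::start(tus)[1] - 1000L),
    strand = "+", gene_id = "nb", gene_name = "NB", biotype = "lincRNA",
    tss = GenomicRanges::start(tus)[1] - 3000L,
    tes = GenomicRanges::start(tus)[1] - 1000L, n_exons = 1L,
    seqlengths = c(chrT = 41L * 30000L))
  # and shrink t02 below the length threshold
  GenomicRanges::width(tus)[2] <- 1500L
  all_tus <- c(tus, neighbor)
  tiers <- rep(c(0, 10, 100, 1000), each = 10)
  track <- track_from_regions(tus, tiers, seqlengths = c(chrT = 41L * 30000L))
  rep1 <- select_nonoverlapping_coding(all_tus, track, seed = 1L)
  expect_false("t01" %in% rep1$members)   # neighbor within 2.5 kb
  expect_false("t02" %in% rep1$members)   # too short
  expect_false("nb" %in% rep1$members)    # not protein-coding
})

test_that("intronless selection keeps single-exon non-histone coding genes", {
  ann <- make_annotation(sim_config(seed = 4))
  rep1 <- select_intronless(ann$genes)
  mc <- S4Vectors::mcols(ann$genes)
  expect_setequal(
    rep1$members,
    mc$gene_id[mc$biotype == "protein_coding" & mc$n_exons == 1L])
  expect_false(any(grepl("^HIST", rep1$members)))
  # multi-exon coding genes are excluded
  expect_false(any(rep1$members %in%
                     mc$gene_id[mc$n_exons > 1L]))
  # idempotence: re-selecting from the selected subset changes nothing
  sel <- ann$genes[mc$gene_id %in% rep1$members]
  expect_setequal(select_intronless(sel)$members, rep1$members)
})

test_that("PROMPT pairing picks the nearest opposite-strand coding gene", {
  tus <- GenomicRanges::GRanges(
    "chrA", IRanges::IRanges(c(10300, 50000, 20000), c(12000, 52000, 21000)),
    strand = c("-", "-", "+"),
    gene_id = c("near", "far", "same_strand_ignored"),
    gene_name = c("A", "B", "C"), biotype = "protein_coding",
    tss = c(12000, 52000, 20000), tes = c(10300, 50000, 21000),
    n_exons = 1L, seqlengths = toy_seqlengths)
  prompt <- GenomicRanges::GRanges(
    "chrA", IRanges::IRanges(10000, 10999), strand = "+",
    gene_id = "p1", tss = 10000, seqlengths = toy_seqlengths)
  pr <- pair_prompts(prompt, tus)
  expect_equal(pr$gene_id, "near")
  expect_equal(pr$tss_distance, 2000)
})

test_that("PROMPT pairing ties break toward the smaller start coordinate", {
  tus <- GenomicRanges::GRanges(
    "chrA", IRanges::IRanges(c(5000, 13000), c(7000, 15000)),
    strand = "-", gene_id = c("left", "right"),
    gene_name = c("L", "R"), biotype = "protein_coding",
    tss = c(7000, 15000), tes = c(5000, 13000), n_exons = 1L,
    seqlengths = toy_seqlengths)
  prompt <- GenomicRanges::GRanges(
    "chrA", IRanges::IRanges(11000, 11000), strand = "+",
    gene_id = "p1", tss = 11000, seqlengths = toy_seqlengths)
  pr <- pair_prompts(prompt, tus)       # both TSSs 4000 bp away
  expect_equal(pr$gene_id, "left")
})

test_that("PROMPT pairing agrees with an all-pairs brute-force search", {
  set.seed(31)
  n_g <- 15; n_p <- 20
  g_tss <- sort(sample.int(90000, n_g))
  g_str <- sample(c("+", "-"), n_g, TRUE)
  tus <- GenomicRanges::GRanges(
    "chrA", IRanges::IRanges(g_tss, g_tss + 999L), strand = g_str,
    gene_id = paste0("g", 1:n_g), gene_name = paste0("G", 1:n_g),
    biotype = "protein_coding",
    tss = ifelse(g_str == "+", g_tss, g_tss + 999L),
    tes = ifelse(g_str == "+", g_tss + 999L, g_tss), n_exons = 1L,
    seqlengths = toy_seqlengths)
  p_tss <- sample.int(90000, n_p)
  p_str <- sample(c("+", "-"), n_p, TRUE)
  prompts <- GenomicRanges::GRanges(
    "chrA", IRanges::IRanges(p_tss, p_tss), strand = p_str,
    gene_id = paste0("p", 1:n_p), tss = p_tss, seqlengths = toy_seqlengths)
  pr <- pair_prompts(prompts, tus)
  tss_of <- S4Vectors::mcols(tus)$tss
  for (i in seq_len(n_p)) {
    cand <- which(g_str == c("+" = "-", "-" = "+")[p_str[i]])
    d <- abs(tss_of[cand] - p_tss[i])
    expect_equal(pr$tss_distance[pr$prompt_id == paste0("p", i)], min(d))
  }
})

test_that("mRNA-lincRNA pairing applies the TSS distance and read filters", {
  sl <- toy_seqlengths
  tus <- GenomicRanges::GRanges(
    "chrA", IRanges::IRanges(c(5000, 4000, 40000, 36500), c(12000, 7000, 47000, 39500)),
    strand = c("+", "-", "+", "-"),
    gene_id = c("mrna1", "linc1", "mrna2", "linc2"),
    gene_name = c("M1", "L1", "M2", "L2"),
    biotype = c("protein_coding", "lincRNA", "protein_coding", "antisense"),
    tss = c(5000, 7000, 40000, 39500),
    tes = c(12000, 4000, 47000, 36500), n_exons = 1L, seqlengths = sl)
  spikes <- GenomicRanges::GRanges(
    "chrA", IRanges::IRanges(c(6000, 6500, 41000, 38000),
                             c(6000, 6500, 41000, 38000)),
    strand = c("+", "-", "+", "-"), seqlengths = sl)
  # control: mrna1 50, linc1 9, mrna2 50, linc2 9 reads
  ctrl <- track_from_regions(spikes, c(50, 9, 50, 9), sl)
  # depleted: linc1 reaches 12 reads, linc2 stays at 9
  dep <- track_from_regions(spikes, c(50, 12, 50, 9), sl)
  pairs <- pair_mrna_lincrna(tus, ctrl, dep)
  expect_equal(nrow(pairs), 2)            # both candidates within 3 kb
  expect_equal(pairs$kept[pairs$linc_id == "linc1"], TRUE)
  expect_equal(pairs$kept[pairs$linc_id == "linc2"], FALSE)
  expect_error(pair_mrna_lincrna(tus, ctrl), "required")
})
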