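test_that("genic/intergenic classification matches a brute-force overlap scan", {
  tus <- tiny_tus()
  set.seed(19)
  st <- sample(seq(1000, 95000, by = 1000), 50)
  origins <- GenomicRanges::GRanges(
    "chrA", IRanges::IRanges(st, st + 999L), seqlengths = toy_seqlengths)
  out <- classify_origins(origins, tus)
  mc <- S4Vectors::mcols(out)
  naive <- vapply(seq_along(origins), function(i) {
    !any(st[i] <= GenomicRanges::end(tus) &
           st[i] + 999L >= GenomicRanges::start(tus) &
           as.character(GenomicRanges::seqnames(tus)) == "chrA")
  }, logical(1))
  expect_equal(mc$is_intergenic, naive)
  # exact partition
  expect_equal(sum(mc$is_intergenic) + sum(!mc$is_intergenic),
               length(origins))
  expect_warning(
    classify_origins(GenomicRanges::GRanges(
      "chrA", IRanges::IRanges(1, 500), seqlengths = toy_seqlengths), tus),
    "not 1 kb")
})

origin_fixture <- function(ctrl_vals, dep_vals) {
  n <- length(ctrl_vals)
  st <- seq(1000, by = 2000, length.out = n)
  origins <- GenomicRanges::GRanges(
    "chrA", IRanges::IRanges(st, st + 999L), seqlengths = toy_seqlengths)
  spikes <- GenomicRanges::GRanges(
    "chrA", IRanges::IRanges(st + 500L, st + 500L), strand = "+",
    seqlengths = toy_seqlengths)
  t_ctrl <- track_from_regions(spikes, ctrl_vals)
  t_dep <- track_from_regions(spikes, dep_vals)
  origin_signal(origins, t_ctrl, t_dep)
}

test_that("origin signal flags positivity and the induction boundary is inclusive", {
  out <- origin_fixture(c(0, 0, 2, 10, 10), c(0, 8, 4, 19, 40))
  mc <- S4Vectors::mcols(out)
  expect_equal(mc$positive_any, c(FALSE, TRUE, TRUE, TRUE, TRUE))
  out <- flag_induced(out, fold = 2)
  mc <- S4Vectors::mcols(out)
  expect_false(mc$induced_2x[1])          # no signal at all
  # depleted-only signal: fold over the half-minimum pseudo-count
  expect_true(mc$induced_2x[2])
  expect_equal(mc$fold_change[2], 0.008 / 0.001)
  expect_true(mc$induced_2x[3])           # exactly 2-fold: "at least"
  expect_false(mc$induced_2x[4])          # 1.9-fold
  expect_true(mc$induced_2x[5])
  expect_error(flag_induced(out, fold = 0), "fold")
})

test_that("raising the fold threshold never grows the induced set", {
  set.seed(23)
  out <- origin_fixture(sample(0:20, 30, TRUE), sample(0:40, 30, TRUE))
  sets <- lapply(c(1, 2, 4, 8), function(f)
    which(S4Vectors::mcols(flag_induced(out, f))$induced_2x))
  for (i in 2:4) expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  # fold = 1: exactly the origins whose depleted signal is positive and
  # at least the control signal (pseudo-count saturates below any signal)
  mc1 <- S4Vectors::mcols(flag_induced(out, 1))
  mc0 <- S4Vectors::mcols(out)
  expect_equal(mc1$induced_2x,
               mc0$signal_depleted > 0 &
                 mc0$signal_depleted >= mc0$signal_ctrl)
})

test_that("nearest ncRNA neighbors match a brute-force scan within 100 kb", {
  cfg <- sim_config(seed = 9)
  ann <- make_annotation(cfg)
  out <- nearest_ncrna(ann$origins, ann$prompts, ann$ernas)
  mc <- S4Vectors::mcols(out)
  # brute force over a sample of origins
  for (i in seq(1, length(out), by = 7)) {
    d <- GenomicRanges::distance(out[i], ann$prompts, ignore.strand = TRUE)
    d <- d[!is.na(d)]
    if (length(d) && min(d) <= 1e5)
      expect_equal(mc$prompt_dist[i], min(d))
    else
      expect_true(is.na(mc$prompt_dist[i]))
  }
  expect_equal(mc$near_ncrna, !is.na(mc$prompt_dist) | !is.na(mc$erna_dist))
  # an origin inside an eRNA window has distance zero
  inside <- nearest_ncrna(
    GenomicRanges::GRanges(
      as.character(GenomicRanges::seqnames(ann$ernas))[1],
      IRanges::IRanges(GenomicRanges::start(ann$ernas)[1],
                       GenomicRanges::start(ann$ernas)[1] + 999L),
      seqlengths = ann$seqlengths),
    ann$prompts, ann$ernas)
  expect_equal(S4Vectors::mcols(inside)$erna_dist, 0)
})

test_that("lncRNA extensions stop at gaps and recover a planted readthrough", {
  sl <- c(chrA = 100000L)
  lnc <- GenomicRanges::GRanges("chrA", IRanges::IRanges(10001, 11000),
                                strand = "+", gene_id = "p1",
                                seqlengths = sl)
  # no depletion-specific signal: annotated span only
  zero <- SignalTrack(IRanges::RleList(chrA = S4Vectors::Rle(0, 100000),
                                       compress = FALSE),
                      IRanges::RleList(chrA = S4Vectors::Rle(0, 100000),
                                       compress = FALSE),
                      stranded = TRUE, library_size = 1e8)
  ext0 <- define_extended_lncrna(zero, zero, lnc)
  expect_equal(GenomicRanges::width(ext0), 1000)
  expect_equal(S4Vectors::mcols(ext0)$extension_bp, 0)

  # signal from TSS to 30 kb with an internal 300-bp gap, then a 2-kb gap
  seg <- GenomicRanges::GRanges(
    "chrA", IRanges::IRanges(c(10001, 20301, 32001), c(20000, 30000, 40000)),
    strand = "+", seqlengths = sl)
  dep <- track_from_regions(seg, c(5, 5, 5), seqlengths = sl)
  ext1 <- define_extended_lncrna(dep, zero, lnc, min_signal = 1,
                                 max_gap = 500)
  expect_equal(GenomicRanges::end(ext1), 30000)  # crosses 300 bp, stops at 2 kb
  ext2 <- define_extended_lncrna(dep, zero, lnc, min_signal = 1,
                                 max_gap = 200)
  expect_equal(GenomicRanges::end(ext2), 20000)  # 300-bp gap now terminal
})

test_that("a simulated readthrough extension is recovered near its planted end", {
  cfg <- sim_config(seed = 14, prompt_extension_bp = 20000)
  ann <- make_annotation(cfg)
  dep <- extract_net_3prime(filter_proper_pairs(
    simulate_netseq(ann, "depleted", 1e6, seed = 15)), ann$seqlengths)
  ctl <- extract_net_3prime(filter_proper_pairs(
    simulate_netseq(ann, "control", 1e6, seed = 16)), ann$seqlengths)
  ext <- define_extended_lncrna(dep, ctl, ann$prompts, min_signal = 1,
                                max_gap = 500)
  got <- S4Vectors::mcols(ext)$extension_bp
  # planted readthrough reaches 19 kb past the 1-kb annotation
  expect_gt(median(got), 19000 - 1500)
  expect_lt(median(got), 19000 + 1500)
})

test_that("origin/extension overlap fractions hit the trivial poles", {
  sl <- toy_seqlengths
  origins <- GenomicRanges::GRanges(
    "chrA", IRanges::IRanges(c(1000, 5000), width = 1000),
    seqlengths = sl)
  inside <- GenomicRanges::GRanges("chrA", IRanges::IRanges(500, 6500),
                                   seqlengths = sl)
  expect_equal(origin_lncrna_overlap(origins, inside), 1)
  away <- GenomicRanges::GRanges("chrA", IRanges::IRanges(50000, 60000),
                                 seqlengths = sl)
  expect_equal(origin_lncrna_overlap(origins, away), 0)
  expect_error(origin_lncrna_overlap(origins[0], away), "empty")
})

test_that("planted origin induction is recovered at 20x coverage", {
  b <- origin_benchmark(seed = 2)
  expect_equal(b$n_induced_true, 40)
  expect_gte(b$n_induced_flagged, 38)
  expect_lte(b$n_false_positive, 2)
  expect_equal(b$n_intergenic + b$n_genic, b$n_total)
})
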