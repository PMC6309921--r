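test_that("the synthetic annotation satisfies the TU invariants", {
  ann <- make_annotation(sim_config(seed = 7))
  gr <- c(ann$genes, ann$prompts)
  mc <- S4Vectors::mcols(gr)
  strd <- as.character(GenomicRanges::strand(gr))
  expect_true(all(GenomicRanges::start(gr) <= GenomicRanges::end(gr)))
  expect_equal(mc$tss, ifelse(strd == "+", GenomicRanges::start(gr),
                              GenomicRanges::end(gr)))
  expect_equal(mc$tes, ifelse(strd == "+", GenomicRanges::end(gr),
                              GenomicRanges::start(gr)))
  for (i in seq_along(gr)) {
    ex <- mc$exons[[i]]
    expect_true(all(GenomicRanges::start(ex) >= GenomicRanges::start(gr)[i]))
    expect_true(all(GenomicRanges::end(ex) <= GenomicRanges::end(gr)[i]))
    if (length(ex) > 1L)
      expect_true(all(GenomicRanges::start(ex)[-1] >
                        GenomicRanges::end(ex)[-length(ex)]))
  }
  # features never overlap each other (origins may sit inside genes)
  feat <- c(GenomicRanges::granges(ann$genes),
            GenomicRanges::granges(ann$prompts),
            GenomicRanges::granges(ann$ernas))
  expect_equal(max(GenomicRanges::countOverlaps(feat, feat,
                                                ignore.strand = TRUE)), 1)
  # divergent pairs: each PROMPT has a coding TSS on the opposite strand
  pr <- pair_prompts(ann$prompts, ann$genes)
  expect_equal(nrow(pr), length(ann$prompts))
  expect_true(all(pr$tss_distance < 3000))
})

test_that("identical configurations reproduce byte-identical libraries", {
  cfg <- sim_config(seed = 42)
  a1 <- make_annotation(cfg); a2 <- make_annotation(cfg)
  expect_identical(a1$truth, a2$truth)
  p1 <- simulate_netseq(a1, "depleted", 2000, seed = 5)
  p2 <- simulate_netseq(a2, "depleted", 2000, seed = 5)
  expect_identical(p1, p2)
  expect_false(identical(
    p1, simulate_netseq(a1, "depleted", 2000, seed = 6)))
})

test_that("every simulated library has exactly the configured depth", {
  ann <- make_annotation(sim_config(seed = 3))
  expect_equal(nrow(simulate_netseq(ann, "control", 1234, seed = 1)), 1234)
  expect_equal(nrow(simulate_fraction_rnaseq(ann, "chromatin", 999,
                                             seed = 1)), 999)
  lib <- simulate_ip_input(ann, "H3K36me3", "control", 500, seed = 1)
  expect_equal(nrow(lib$ip), 500)
  expect_equal(nrow(lib$input), 500)
  expect_error(simulate_netseq(ann, "control", 0, seed = 1), "depth")
})

test_that("planted induction shows up in raw per-class count ratios", {
  ann <- make_annotation(sim_config(seed = 4, prompt_fold = 4))
  d <- 2e5
  ctrl <- simulate_netseq(ann, "control", d, seed = 21)
  dep <- simulate_netseq(ann, "depleted", d, seed = 22)
  t <- ann$truth
  pr <- t[t$class == "PROMPT", ]
  count_in <- function(p, reg) {
    sum(p$chrom == reg$chrom &
          pmin(p$r1_start, p$r2_start) >= reg$sim_start - 200 &
          pmax(p$r1_end, p$r2_end) <= reg$sim_end + 200)
  }
  rc <- sum(vapply(seq_len(nrow(pr)), function(i) count_in(ctrl, pr[i, ]),
                   numeric(1)))
  rd <- sum(vapply(seq_len(nrow(pr)), function(i) count_in(dep, pr[i, ]),
                   numeric(1)))
  ratio <- (rd / rc)
  expect_gt(ratio, 3)
  expect_lt(ratio, 5)
})

test_that("duplicate flagging matches the requested fraction exactly", {
  ann <- make_annotation(sim_config(seed = 3))
  lib <- simulate_ip_input(ann, "H3K36me3", "control", 2000, seed = 2,
                           dup_fraction = 0.25)
  expect_equal(sum(lib$ip$duplicate), 500)
  kept <- filter_proper_pairs(lib$ip, drop_duplicates = TRUE)
  expect_equal(nrow(kept), 1500)
})

test_that("IP enrichment of 1 leaves nothing after input subtraction", {
  cfg <- sim_config(seed = 8, ip_enrichment = list(
    flatmark = list(control = c(coding = 1), depleted = c(coding = 1))))
  ann <- make_annotation(cfg)
  lib <- simulate_ip_input(ann, "flatmark", "control", 5e4, seed = 3)
  sl <- ann$seqlengths
  ip_t <- coverage_track(filter_proper_pairs(lib$ip), sl, stranded = FALSE)
  in_t <- coverage_track(filter_proper_pairs(lib$input), sl, stranded = FALSE)
  coding <- ann$genes[S4Vectors::mcols(ann$genes)$biotype == "protein_coding"]
  ipc <- region_basecount(ip_t, coding, "both")
  inc <- region_basecount(in_t, coding, "both")
  # normalized difference hovers around zero: most regions impute
  q <- ip_minus_input_quant(cbind(ipc), cbind(inc), 5e4, 5e4,
                            GenomicRanges::width(coding))
  expect_gt(sum(q$imputed) + q$n_dropped, length(coding) * 0.3)
})

test_that("written annotation files parse back through the standard readers", {
  ann <- make_annotation(sim_config(seed = 10, n_coding = 6L, n_prompt = 2L,
                                    n_erna = 3L, n_origins = 8L,
                                    n_lincrna = 2L, n_intronless = 2L,
                                    n_histone = 1L, n_snrna = 2L))
  paths <- write_annotation(ann, tempfile())
  prompts <- read_bed(paths[["prompts"]])
  expect_equal(length(prompts), 2)
  expect_equal(as.character(GenomicRanges::strand(prompts)),
               as.character(GenomicRanges::strand(ann$prompts)))
  origins <- read_bed(paths[["origins"]])
  expect_equal(GenomicRanges::width(origins), rep(1000, 8))
})
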