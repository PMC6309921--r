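test_that("region base counts match the naive per-base oracle", {
  gr <- GenomicRanges::GRanges("chrA", IRanges::IRanges(1001, 1100),
                               strand = "+", seqlengths = toy_seqlengths)
  tr <- track_from_regions(gr, 2)
  expect_equal(region_basecount(tr, gr, "region"), 200)  # 2 x 100 bp
  empty <- SignalTrack(
    IRanges::RleList(chrA = S4Vectors::Rle(0, 100000),
                     chrB = S4Vectors::Rle(0, 80000), compress = FALSE),
    stranded = FALSE, library_size = 1)
  expect_equal(region_basecount(empty, gr), 0)

  # sparse random track, 50 random regions, both strands
  set.seed(11)
  spikes <- GenomicRanges::GRanges(
    "chrA", IRanges::IRanges(sample.int(50000, 300), width = 1),
    strand = sample(c("+", "-"), 300, TRUE), seqlengths = toy_seqlengths)
  trk <- track_from_regions(spikes, sample.int(5, 300, TRUE))
  q_start <- sample.int(49000, 50)
  regions <- GenomicRanges::GRanges(
    "chrA", IRanges::IRanges(q_start, q_start + 999L),
    strand = sample(c("+", "-"), 50, TRUE), seqlengths = toy_seqlengths)
  got <- region_basecount(trk, regions, "region")
  for (i in 1:50)
    expect_equal(got[i], oracle_basecount(
      trk, "chrA", q_start[i], q_start[i] + 999L,
      as.character(GenomicRanges::strand(regions))[i]))
  both <- region_basecount(trk, regions, "both")
  for (i in 1:50)
    expect_equal(both[i], oracle_basecount(trk, "chrA", q_start[i],
                                           q_start[i] + 999L, "*"))
  expect_error(region_basecount(
    trk, GenomicRanges::GRanges("chrZ", IRanges::IRanges(1, 10))),
    "unknown chromosome")
})

test_that("normalization follows count x (1e8/library) / length", {
  q <- normalize_quant(100, 1e8, 1000)
  expect_equal(q$value, 0.1)
  expect_equal(q$log2_value, log2(0.1), tolerance = 1e-12)
  q0 <- normalize_quant(0, 1e8, 1000)
  expect_equal(q0$value, 0)
  expect_true(is.na(q0$log2_value))
  expect_false(q0$imputed)
  expect_error(normalize_quant(1, 0, 100), "library_size")
  expect_error(normalize_quant(1, 100, 0), "length_bp")

  # batch of 20 random records vs direct formula re-evaluation
  set.seed(3)
  cnt <- runif(20, 0, 1e4); lib <- runif(20, 1e6, 1e8)
  len <- sample.int(1e4, 20)
  q <- normalize_quant(cnt, lib, len)
  expect_equal(q$value, cnt * (1e8 / lib) / len)

  # scaling invariance: scaling counts and library together is a no-op
  q2 <- normalize_quant(cnt * 3, lib * 3, len)
  expect_equal(q2$value, q$value, tolerance = 1e-12)
})

test_that("IP-minus-input drops all-nonpositive regions and imputes min/2", {
  # region 1: ip = 2x input; region 2: weak; region 3: ip = input (zero);
  # region 4: nonpositive everywhere -> dropped
  ip <- matrix(c(400, 150, 100, 50), ncol = 1)
  input <- matrix(c(200, 100, 100, 80), ncol = 1)
  q <- ip_minus_input_quant(ip, input, 1e8, 1e8, length_bp = 1000)
  expect_equal(q$n_dropped, 2)     # zero-difference and negative regions
  expect_true(all(q$value > 0))
  expect_equal(sum(q$imputed), 0)

  # the documented example: surviving values {2.0, 0.5, <=0} -> 0.25
  ip2 <- matrix(c(3000, 1500, 800, 2000), ncol = 1)
  input2 <- matrix(c(1000, 1000, 1000, 2000), ncol = 1)
  # values: 2.0, 0.5, -0.2, 0.0 per kb; last two rows positive in sample 2
  ip2 <- cbind(ip2, c(3000, 1500, 1200, 2400))
  input2 <- cbind(input2, c(1000, 1000, 1000, 2000))
  q2 <- ip_minus_input_quant(ip2, input2, c(1e8, 1e8), c(1e8, 1e8),
                             length_bp = 1000)
  expect_equal(q2$n_dropped, 0)
  expect_equal(q2$value[3, 1], 0.25)   # min positive (0.5) / 2
  expect_equal(q2$value[4, 1], 0.25)
  expect_true(all(q2$imputed[3:4, 1]))
  expect_equal(sum(q2$imputed), sum(c(ip2 - input2)[1:4] <= 0))
  # invariant: nothing nonpositive survives
  expect_true(all(q2$value > 0))
})

test_that("class windows follow the per-class definitions, strand-aware", {
  sl <- c(chrA = 1e6)
  pr <- GenomicRanges::GRanges("chrA", IRanges::IRanges(10000, 10999),
                               strand = "+", seqlengths = sl)
  w <- class_window(pr, "PROMPT")
  expect_equal(GenomicRanges::start(w), 10000)
  expect_equal(GenomicRanges::width(w), 3000)
  # minus-strand PROMPT extends leftward from its TSS
  pr2 <- GenomicRanges::GRanges("chrA", IRanges::IRanges(9001, 10000),
                                strand = "-", seqlengths = sl)
  w2 <- class_window(pr2, "PROMPT")
  expect_equal(GenomicRanges::end(w2), 10000)
  expect_equal(GenomicRanges::width(w2), 3000)
  # eRNA: center +/- 2 kb
  er <- GenomicRanges::GRanges("chrA", IRanges::IRanges(50000, 50000),
                               seqlengths = sl)
  w3 <- class_window(er, "eRNA")
  expect_equal(GenomicRanges::width(w3), 4000)
  expect_equal(GenomicRanges::start(w3), 48000)
  # CRI window is 5 kb; TU classes keep the full span
  expect_equal(GenomicRanges::width(class_window(pr, "CRI_PROMPT")), 5000)
  expect_equal(GenomicRanges::width(class_window(pr, "lincRNA")), 1000)
  expect_error(class_window(pr, "enhancerish"), "unknown region class")
})

test_that("CRI is the log2 chromatin/nucleoplasm ratio and antisymmetric", {
  expect_equal(chromatin_retention_index(1, 1)$cri, 0)
  expect_equal(chromatin_retention_index(4, 1)$cri, 2)
  a <- c(4, 2, 0.5, 1); b <- c(1, 2, 2, 8)
  expect_equal(chromatin_retention_index(a, b)$cri,
               -chromatin_retention_index(b, a)$cri)
  # zero denominators use the half-minimum pseudo-value and are flagged
  z <- chromatin_retention_index(c(1, 2), c(0, 4))
  expect_true(z$imputed[1])
  expect_equal(z$cri[1], log2(1 / 2))    # pseudo = 4/2
  expect_error(chromatin_retention_index(1:3, 1:2), "different regions")
})

test_that("mark ratios recover planted enrichment, with Pol II scaling", {
  expect_equal(mark_ratio(2, 2)$ratio, 0)
  expect_equal(mark_ratio(8, 1)$ratio, 3)
  expect_equal(mark_ratio(8, 2, polii_value = 2)$ratio, 1)
  r <- mark_ratio(c(4, 0), c(1, 1))
  expect_true(r$imputed[2])
})

test_that("binned correlations are rank-based and detect planted structure", {
  set.seed(13)
  vals <- runif(10, 1, 100)
  bins <- GenomicRanges::GRanges(
    "chrA", IRanges::IRanges(seq(1, 90001, by = 10000), width = 10000),
    strand = "+", seqlengths = toy_seqlengths)
  t1 <- track_from_regions(bins, vals)
  t1@label <- "a"
  m <- binned_correlation(list(t1, t1), bin_bp = 10000)
  expect_equal(m[1, 2], 1)
  # a monotone transform preserves ranks exactly
  t2 <- track_from_regions(bins, vals^2); t2@label <- "sq"
  expect_equal(binned_correlation(list(t1, t2))[1, 2], 1)
  # complementary occupancy (active vs silenced mark) anti-correlates
  t3 <- track_from_regions(bins, max(vals) + 1 - vals); t3@label <- "anti"
  expect_lt(binned_correlation(list(t1, t3))[1, 2], -0.8)
  expect_error(binned_correlation(list(t1)), "at least two")
})

test_that("Wilcoxon wrappers behave at the extremes and hold type-I error", {
  same <- c(1, 2, 3, 4, 5)
  r <- compare_groups(same, same)
  expect_gt(r$p_value, 0.9)
  r2 <- compare_groups(1:10, 101:110)
  expect_lt(r2$p_value, 0.001)
  expect_error(compare_groups(rep(1, 5), rep(1, 5)), "tied")
  expect_error(compare_groups(1:2, 1:5), "at least 3")
  expect_error(compare_groups(1:5, 1:4, paired = TRUE), "equal group sizes")
  # 500 null simulations at n = 20: rejection rate near alpha = 0.05
  set.seed(99)
  rej <- mean(replicate(500, {
    compare_groups(rnorm(20), rnorm(20))$p_value < 0.05
  }))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})
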