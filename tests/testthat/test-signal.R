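test_that("window copy number is the overlap-weighted mean of segments", {
  layout <- flat_layout(length = 3e4)  # 3 windows of 10 kb
  segs <- cn_segments(data.frame(chrom = "chr1",
                                 start = c(0, 15000),
                                 end = c(15000, 20000),
                                 cn = c(2, 3)))
  cn <- assign_window_cn(segs, layout)
  expect_equal(cn$cn[1], 2)      # fully covered by CN 2
  expect_equal(cn$cn[2], 2.5)    # half CN 2, half CN 3
  expect_true(is.na(cn$cn[3]))   # no covering segment -> missing
})

test_that("uniform whole-chromosome segments give a constant profile", {
  layout <- toy_layout()
  segs <- cn_segments(data.frame(chrom = c("chrA", "chrB", "chrY"),
                                 start = 0, end = c(1e5, 8e4, 5.5e4),
                                 cn = c(2, 2, 1)))
  cn <- assign_window_cn(segs, layout)
  expect_equal(cn$cn, rep(c(2, 2, 1), c(10, 8, 5)))
})

test_that("filtering excludes low, missing and unmappable copy number with reasons", {
  # 4 windows; a 1-bp excluded region overlaps window 4
  layout <- genome_layout(data.frame(name = "chr1", length = 4e4,
                                     ploidy = 2),
                          window_size = 10000,
                          excluded_regions = data.frame(
                            chrom = "chr1", start = 30000, end = 30001))
  cn <- cn_profile(c(0.2, 0.3, NA, 2), layout)
  mask <- filter_windows(layout, cn)
  expect_equal(mask$retained, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(mask$reason,
               c("low_cn", NA, "missing_cn", "unmappable"))
})

test_that("effective length follows the ploidy-scaled copy-number weighting", {
  # uniform C = P: plain retained length
  expect_equal(effective_length(rep(10000, 5), rep(2, 5), 2), 50000)
  # two 10-kb windows, C = 2 and 4, P = 2
  expect_equal(effective_length(c(10000, 10000), c(2, 4), 2), 30000)
  # haploid chromosome, C = 1
  expect_equal(effective_length(rep(10000, 5), rep(1, 5), 1), 50000)
  expect_equal(effective_length(numeric(0), numeric(0), 2), 0)
  expect_error(effective_length(10000, 2, 0), "ploidy")
})

test_that("normalized signal evaluates the closed form", {
  # one diploid 1-Mb chromosome at C = 2 everywhere: L = 1e6;
  # put T = 100 in window 1 and pad R to 1000
  layout <- flat_layout(length = 1e6)
  counts <- numeric(100)
  counts[1] <- 100
  counts[2:10] <- 100  # R = 1000
  tr <- window_track(counts, layout)
  cn <- neutral_cn(layout)
  s <- normalized_signal(tr, cn)
  expect_equal(s$L, 1e6)
  expect_equal(s$R, 1000)
  expect_equal(s$signal[1], (100 / 2) * (1e6 / 1000))  # = 50000
  expect_equal(s$signal[11], 0)  # T = 0 -> S = 0
})

test_that("signal is invariant under uniform depth scaling and monotone in T", {
  layout <- toy_layout()
  set.seed(5)
  counts <- rpois(layout$n_windows, 300)
  cn <- neutral_cn(layout)
  s1 <- normalized_signal(window_track(counts, layout), cn)
  s7 <- normalized_signal(window_track(counts * 7, layout), cn)
  expect_equal(s1$signal, s7$signal, tolerance = 1e-12)
  # strictly increasing in T with C, L, R fixed
  counts2 <- counts
  counts2[3] <- counts2[3] + 1
  s2 <- normalized_signal(window_track(counts2, layout, total_reads = s1$R),
                          cn)
  expect_gt(s2$signal[3], s1$signal[3])
})

test_that("vectorized signal matches the brute-force per-window oracle", {
  layout <- toy_layout(excluded_regions = data.frame(
    chrom = "chrB", start = 25000, end = 26000))
  set.seed(9)
  counts <- rpois(layout$n_windows, 200)
  cnv <- sample(c(0.1, 1, 2, 2, 3), layout$n_windows, replace = TRUE)
  cnv[4] <- NA
  cn <- cn_profile(cnv, layout)
  s <- normalized_signal(window_track(counts, layout), cn)
  oracle <- brute_force_signal(counts, cnv, layout, s$retained)
  expect_equal(s$signal, oracle, tolerance = 1e-12)
})

test_that("signal requires positive depth and matching grids", {
  layout <- toy_layout()
  other <- flat_layout()
  cn <- neutral_cn(layout)
  expect_error(window_track(rep(0, layout$n_windows), layout),
               "total_reads")
  tr_other <- window_track(rpois(other$n_windows, 10), other)
  expect_error(normalized_signal(tr_other, cn), "layout")
})

test_that("signal tables assemble per-window quantities", {
  layout <- flat_layout(length = 3e4)
  counts <- c(10, 0, 5)
  tr <- window_track(counts, layout)
  cn <- neutral_cn(layout)
  s <- normalized_signal(tr, cn)
  tab <- signal_table(tr, cn, s)
  expect_equal(tab$count, counts)
  expect_true(all(tab$retained))
})
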