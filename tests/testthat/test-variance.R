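# build a pair of signal tracks on the flat layout from explicit values
signal_pair <- function(vc, vp, layout = flat_layout(length = 1e4 * length(vc))) {
  cn <- neutral_cn(layout)
  tc <- window_track(pmax(vc, 1), layout, clone_id = "clone")
  tp <- window_track(pmax(vp, 1), layout, clone_id = "parental")
  sc <- normalized_signal(tc, cn)
  sp <- normalized_signal(tp, cn)
  # overwrite signals with the requested values to isolate fold-change logic
  sc$signal <- as.numeric(vc)
  sp$signal <- as.numeric(vp)
  list(sc = sc, sp = sp)
}

test_that("fold change is the ratio to the parental signal", {
  p <- signal_pair(c(400, 100, 100), c(100, 100, 0))
  fc <- fold_change(p$sc, p$sp)
  expect_equal(fc$fc[1], 4)
  expect_equal(fc$log2fc[1], 2)
  expect_equal(fc$fc[2], 1)
  expect_equal(fc$log2fc[2], 0)
  expect_true(is.na(fc$fc[3]))
  expect_equal(fc$reason[3], "zero_signal")
})

test_that("a clone compared with itself gives fold change exactly 1", {
  layout <- toy_layout()
  set.seed(21)
  counts <- rpois(layout$n_windows, 400)
  cn <- neutral_cn(layout)
  s <- normalized_signal(window_track(counts, layout), cn)
  fc <- fold_change(s, s, counts_c = window_track(counts, layout),
                    counts_p = window_track(counts, layout))
  defined <- !is.na(fc$fc)
  expect_true(any(defined))
  expect_true(all(fc$fc[defined] == 1))
  expect_true(all(fc$log2fc[defined] == 0))
})

test_that("the support rule requires more than the threshold in either sample", {
  expect_true(support_mask(150, 250))     # parent exceeds 200
  expect_false(support_mask(200, 200))    # strictly greater than
  expect_true(support_mask(201, 0))
  expect_equal(support_mask(c(150, 200, 201), c(250, 200, 0)),
               c(TRUE, FALSE, TRUE))
})

test_that("intra-clone statistics use the unbiased variance per chromosome", {
  layout <- flat_layout(length = 1e5)  # 10 windows, one chromosome
  p <- signal_pair(rep(2^0.7, 10), rep(1, 10), layout)
  fc <- fold_change(p$sc, p$sp)
  st <- intra_clone_stats(fc)
  expect_equal(st$mean_log2fc, 0.7)
  expect_equal(st$var_log2fc, 0)

  p <- signal_pair(c(0.5, 2), c(1, 1))
  st <- intra_clone_stats(fold_change(p$sc, p$sp))
  expect_equal(st$mean_log2fc, 0)
  expect_equal(st$var_log2fc, 2)   # n - 1 = 1 divisor
})

test_that("chromosomes with fewer than two supported windows get no variance", {
  layout <- flat_layout(length = 2e4)
  p <- signal_pair(c(2, 2), c(1, 1), layout)
  fc <- fold_change(p$sc, p$sp,
                    counts_c = window_track(c(500, 10), layout),
                    counts_p = window_track(c(500, 10), layout))
  st <- intra_clone_stats(fc)
  expect_equal(st$n_windows, 1L)
  expect_true(is.na(st$var_log2fc))
})

test_that("inter-clone variance is the across-clone variance per window", {
  layout <- flat_layout(length = 2e4)
  mk <- function(v) {
    p <- signal_pair(v, rep(1, 2), layout)
    fold_change(p$sc, p$sp)
  }
  # window 1: log2fc 0, 0, 3 across three clones -> variance 3
  fcs <- list(mk(c(1, 1)), mk(c(1, 1)), mk(c(8, 1)))
  iv <- inter_clone_variance(fcs)
  expect_equal(iv$variance[1], 3)
  expect_equal(iv$variance[2], 0)
  expect_equal(iv$n_clones, c(3, 3))
})

test_that("clones failing the copy-number rule drop out of a window", {
  layout <- flat_layout(length = 2e4)
  mk <- function(v) {
    p <- signal_pair(v, rep(1, 2), layout)
    fold_change(p$sc, p$sp)
  }
  fcs <- list(mk(c(2, 2)), mk(c(4, 4)), mk(c(8, 8)))
  cns <- list(cn_profile(c(2, 2), layout), cn_profile(c(0.3, 2), layout),
              cn_profile(c(0.2, 2), layout))
  iv <- inter_clone_variance(fcs, cns)
  # window 1: only clone 1 passes CN > 0.3 (0.3 itself fails the strict rule)
  expect_equal(iv$n_clones[1], 1)
  expect_true(is.na(iv$variance[1]))
  expect_equal(iv$n_clones[2], 3)
})

test_that("Mann-Whitney matches exact enumeration on small groups", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p.value, 0.1)  # 2 * (1 / choose(6, 3) favourable sets)
  # identical multisets: no evidence either way
  res <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$p.value, 1)
  # all values tied: degenerate, p = 1
  res <- mann_whitney(rep(0, 5), rep(0, 7))
  expect_equal(res$p.value, 1)
  expect_error(mann_whitney(numeric(0), 1:3), "empty")
})

test_that("two-sided p is symmetric under swapping the groups", {
  set.seed(13)
  for (i in 1:5) {
    x <- rnorm(sample(3:20, 1))
    y <- rnorm(sample(3:20, 1), mean = runif(1, -1, 1))
    a <- mann_whitney(x, y)
    b <- mann_whitney(y, x)
    expect_equal(a$p.value, b$p.value, tolerance = 1e-12)
    expect_equal(a$U + b$U, length(x) * length(y))
  }
})

test_that("log fold-change variance is shift-invariant and scales quadratically", {
  set.seed(17)
  for (i in 1:10) {
    x <- rnorm(20)
    k <- runif(1, 0.5, 3)
    expect_equal(var(x + 5), var(x), tolerance = 1e-12)
    expect_equal(var(k * x), k^2 * var(x), tolerance = 1e-12)
  }
})

test_that("chromosome group comparison runs on both sampling units", {
  intra <- data.frame(chrom = rep(c("chrY", "chr1", "chr2"), each = 4),
                      var_log2fc = c(5, 6, 7, 8, 1, 2, 1.5, 2.5,
                                     1.2, 2.2, 1.7, 2.7))
  res <- compare_chromosome_groups(intra, "chrY", c("chr1", "chr2"))
  expect_lt(res$p.value, 0.05)
  expect_equal(res$n_a, 4)
  perwin <- data.frame(chrom = rep(c("chrY", "chr1"), each = 30),
                       variance = c(rnorm(30, 4), rnorm(30, 1)))
  res <- compare_chromosome_groups(perwin, "chrY", "chr1",
                                   unit = "per_window")
  expect_lt(res$p.value, 0.001)
  expect_error(compare_chromosome_groups(intra, character(0), "chr1"),
               "non-empty")
})

test_that("Spearman correlation matches rank-then-Pearson arithmetic", {
  expect_equal(assay_fold_change_correlation(1:10, (1:10)^2)$rho, 1)
  expect_equal(assay_fold_change_correlation(1:10, -(1:10)^3)$rho, -1)
  set.seed(31)
  x <- rnorm(10); y <- rnorm(10)
  res <- assay_fold_change_correlation(x, y)
  expect_equal(res$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_error(assay_fold_change_correlation(c(1, 2), c(2, 1)), "3")
})
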