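test_that("the cohort generator is deterministic under a fixed seed", {
  a <- simulate_cohort(small_sim_config(seed = 5))
  b <- simulate_cohort(small_sim_config(seed = 5))
  expect_identical(a, b)
  c <- simulate_cohort(small_sim_config(seed = 6))
  expect_false(identical(a$tracks$parental$ATAC$counts,
                         c$tracks$parental$ATAC$counts))
})

test_that("simulation does not disturb the caller's random stream", {
  set.seed(123)
  x1 <- runif(3)
  set.seed(123)
  invisible(simulate_cohort(small_sim_config(seed = 99)))
  x2 <- runif(3)
  expect_identical(x1, x2)
})

test_that("zero magnitude plants no perturbation anywhere", {
  sim <- simulate_cohort(small_sim_config(seed = 2,
                                          perturb_magnitude = 0))
  expect_true(all(sim$truth$u_ATAC == 0))
  expect_true(all(sim$truth$u_H3K27ac == 0))
})

test_that("perturbations are confined to the transit chromosome", {
  sim <- simulate_cohort(small_sim_config(seed = 3))
  off <- sim$truth$chrom != "chrY"
  expect_true(all(sim$truth$u_ATAC[off] == 0))
  expect_true(all(sim$truth$u_H3K27ac[off] == 0))
  expect_gt(sum(sim$truth$u_ATAC != 0), 0)
})

test_that("with f = 1 and delta = ln 2 the mean multiplicative effect is cosh(ln 2)", {
  sim <- simulate_cohort(small_sim_config(seed = 8, n_clones = 100,
                                          perturb_fraction = 1,
                                          assays = "ATAC"))
  u <- sim$truth$u_ATAC[sim$truth$chrom == "chrY"]
  expect_true(all(u %in% c(log(2), -log(2))))
  expect_equal(mean(exp(u)), cosh(log(2)), tolerance = 0.05)  # = 1.25
})

test_that("simulated count means follow depth * (C/P) * exp(lambda + u)", {
  sim <- simulate_cohort(small_sim_config(
    seed = 4, n_clones = 50, perturb_magnitude = 0, assays = "ATAC",
    cn_events = list(list(clone = 1, chrom = "chr1",
                          start = 0, end = 2e5, cn = 3))))
  lam <- sim$baseline_log
  win <- layout_windows(sim$layout)
  # across clones 2..50 (neutral CN) the per-window mean tracks the baseline
  m <- rowMeans(sapply(2:50, function(j)
    sim$tracks$clones[[j]]$ATAC$counts))
  ratio <- m / (500 * exp(lam))
  expect_equal(mean(ratio), 1, tolerance = 0.03)
  # the CN = 3 event on a diploid chromosome scales clone 1 by 1.5
  ev <- win$chrom == "chr1" & win$start < 2e5
  scale_est <- mean(sim$tracks$clones[[1]]$ATAC$counts[ev]) /
    mean(500 * exp(lam[ev]))
  expect_equal(scale_est, 1.5, tolerance = 0.1)
})

test_that("overdispersion widens counts relative to Poisson", {
  cfg_nb <- small_sim_config(seed = 12, n_clones = 1, assays = "ATAC",
                             perturb_magnitude = 0, baseline_sd = 0)
  cfg_po <- small_sim_config(seed = 12, n_clones = 1, assays = "ATAC",
                             perturb_magnitude = 0, baseline_sd = 0,
                             nb_dispersion = 0)
  x_nb <- simulate_cohort(cfg_nb)$tracks$parental$ATAC$counts
  x_po <- simulate_cohort(cfg_po)$tracks$parental$ATAC$counts
  # NB variance = mu + phi mu^2 = 500 + 0.05 * 500^2 = 13000 vs 500
  expect_gt(var(x_nb), 4 * var(x_po))
})

test_that("the planted rank coupling on perturbed windows hits its closed form", {
  # two-point effects with |rho| < sqrt(1 - rho^2): within a sign class of
  # u_atac, the mark's sign is set by the independent component, giving a
  # latent Spearman of 1/sqrt(5) regardless of rho in (0, 0.707);
  # pinned here as a regression value derived by brute-force simulation
  sim <- simulate_cohort(sim_config(
    layout = genome_layout(data.frame(name = "chrY", length = 5e7,
                                      ploidy = 1), window_size = 10000),
    transit_chrom = "chrY", n_clones = 2, perturb_fraction = 0.5,
    seed = 14))
  tr <- sim$truth
  pert <- tr$u_ATAC != 0
  rho <- suppressWarnings(cor(tr$u_ATAC[pert], tr$u_H3K27ac[pert],
                              method = "spearman"))
  expect_equal(rho, 1 / sqrt(5), tolerance = 0.03)
})

test_that("truth tables round-trip through TSV", {
  sim <- simulate_cohort(small_sim_config(seed = 10))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth(sim$truth, path)
  back <- read_truth(path)
  expect_equal(back$u_ATAC, sim$truth$u_ATAC, tolerance = 1e-12)
  expect_identical(back$chrom, sim$truth$chrom)
  expect_equal(back$cn, sim$truth$cn)
})

test_that("invalid configurations are rejected", {
  expect_error(small_sim_config(perturb_fraction = 1.2), "perturb_fraction")
  expect_error(small_sim_config(assay_coupling = 2), "assay_coupling")
  expect_error(small_sim_config(nb_dispersion = -1), "nb_dispersion")
  expect_error(small_sim_config(transit_chrom = "chr99"), "layout")
  expect_error(small_sim_config(cn_events = list(list(clone = 1))),
               "cn_event")
})

test_that("recovery evaluation refuses analyses from a different run", {
  sim1 <- simulate_cohort(small_sim_config(seed = 1, assays = "ATAC"))
  sim2 <- simulate_cohort(small_sim_config(seed = 2, assays = "ATAC"))
  an2 <- analyze_cohort(sim2)
  expect_error(evaluate_recovery(sim1, analysis = an2), "different runs")
})

test_that("recovery metrics identify a strongly perturbed transit chromosome", {
  sim <- simulate_cohort(small_sim_config(seed = 15, depth = 800))
  rec <- evaluate_recovery(sim)
  expect_true(rec$transit_rank_first)
  expect_lt(rec$group_p, 0.01)
  expect_gt(rec$precision_at_k, 0.2)
  expect_gt(rec$n_pairs, 20)
})
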