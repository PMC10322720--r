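# small deterministic fixtures shared across test files

# 3-chromosome toy genome: two diploid chromosomes and a haploid one whose
# analysed span is truncated (23 windows of 10 kb in total)
toy_layout <- function(excluded_regions = NULL, window_size = 10000) {
  genome_layout(data.frame(
    name = c("chrA", "chrB", "chrY"),
    length = c(1e5, 8e4, 5.5e4),
    ploidy = c(2, 2, 1),
    analysis_limit = c(NA, NA, 5e4)),
    window_size = window_size, excluded_regions = excluded_regions)
}

# single diploid chromosome fully covered at neutral copy number
flat_layout <- function(length = 1e6, window_size = 10000) {
  genome_layout(data.frame(name = "chr1", length = length, ploidy = 2),
                window_size = window_size)
}

neutral_cn <- function(layout, clone_id = "sample") {
  ct <- layout$chromosomes
  cn_profile(rep(ct$ploidy, ct$n_windows), layout, clone_id = clone_id)
}

# compact simulation setup for unit tests (fast, ~70 windows)
small_sim_config <- function(..., transit_chrom = "chrY") {
  layout <- genome_layout(data.frame(
    name = c("chr1", "chrY"), length = c(5e5, 2e5),
    ploidy = c(2, 1)), window_size = 10000)
  sim_config(layout = layout, transit_chrom = transit_chrom, ...)
}

# independent brute-force recomputation of the normalized signal,
# window by window, used as the oracle for the vectorized implementation
brute_force_signal <- function(counts, cn, layout, retained,
                               total_reads = sum(counts)) {
  win <- layout_windows(layout)
  ct <- layout$chromosomes
  L <- 0
  for (k in seq_len(nrow(ct))) {
    l <- 0
    for (i in seq_len(nrow(win))) {
      if (win$chrom[i] == ct$name[k] && retained[i])
        l <- l + (win$end[i] - win$start[i]) * cn[i]
    }
    L <- L + l / ct$ploidy[k]
  }
  s <- rep(NA_real_, nrow(win))
  for (i in seq_len(nrow(win))) {
    if (retained[i]) s[i] <- (counts[i] / cn[i]) * (L / total_reads)
  }
  s
}
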