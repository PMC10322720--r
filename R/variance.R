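#' Clone-versus-parental signal fold change
#'
#' The signal fold change of a clone c in window i is
#' `F(c,i) = S(c,i) / S(p,i)` with p the parental line; `log2F` is its
#' log2. F is defined only on windows retained in both tracks where both
#' signals are positive (unless a pseudocount is supplied); windows failing
#' the positivity requirement carry reason `"zero_signal"`.
#'
#' When the raw count tracks are supplied, the low-count support rule is
#' evaluated alongside: a window is *supported* iff the clone or the parent
#' has more than `support_threshold` reads (strictly more; default 200).
#' High apparent fold changes in windows where both samples have few reads
#' are dominated by counting noise, and all variance summaries in this
#' package restrict to supported windows.
#'
#' @param signal_c clone `signal_track`.
#' @param signal_p parental `signal_track` on the same layout.
#' @param counts_c,counts_p optional `window_track`s used for the support
#'   rule; when omitted every defined window is marked supported.
#' @param support_threshold read-count threshold of the support rule.
#' @param pseudocount added to both signals before the ratio; default 0
#'   (off), in which case zero-signal windows are undefined rather than
#'   shrunk.
#' @return object of class `fc_track` with `$fc`, `$log2fc`, `$supported`
#'   (logical), `$reason`.
#' @export
fold_change <- function(signal_c, signal_p, counts_c = NULL,
                        counts_p = NULL, support_threshold = 200,
                        pseudocount = 0) {
  stopifnot(inherits(signal_c, "signal_track"),
            inherits(signal_p, "signal_track"))
  .check_same_layout(signal_c$layout, signal_p$layout,
                     "clone and parental signal tracks")
  n <- length(signal_c$signal)
  both <- signal_c$retained & signal_p$retained
  sc <- signal_c$signal + pseudocount
  sp <- signal_p$signal + pseudocount
  ok <- both & !is.na(sc) & !is.na(sp) & sc > 0 & sp > 0
  fc <- rep(NA_real_, n)
  fc[ok] <- sc[ok] / sp[ok]
  reason <- rep(NA_character_, n)
  reason[!both] <- "excluded"
  reason[both & !ok] <- "zero_signal"

  if (!is.null(counts_c) && !is.null(counts_p)) {
    .check_same_layout(signal_c$layout, counts_c$layout,
                       "signal and count tracks")
    supported <- support_mask(counts_c, counts_p,
                              threshold = support_threshold)
  } else supported <- rep(TRUE, n)
  supported <- supported & ok

  structure(list(clone_id = signal_c$clone_id, assay = signal_c$assay,
                 parent_id = signal_p$clone_id,
                 fc = fc, log2fc = log2(fc), supported = supported,
                 reason = reason, layout = signal_c$layout),
            class = "fc_track")
}

#' Low-count support mask
#'
#' A window is supported iff `max(T_clone, T_parent) > threshold`
#' (strictly greater): windows in which *neither* sample exceeds the
#' threshold are excluded from variance calculations, because their fold
#' changes are dominated by sampling error.
#'
#' @param counts_c,counts_p `window_track`s (or bare numeric vectors of
#'   equal length).
#' @param threshold integer read threshold (default 200).
#' @return logical vector per window.
#' @export
support_mask <- function(counts_c, counts_p, threshold = 200) {
  tc <- if (inherits(counts_c, "window_track")) counts_c$counts else counts_c
  tp <- if (inherits(counts_p, "window_track")) counts_p$counts else counts_p
  if (length(tc) != length(tp))
    stop("count vectors differ in length")
  pmax(tc, tp) > threshold
}

#' Per-chromosome intra-clone fold-change statistics
#'
#' Mean and unbiased (n - 1) sample variance of log2 fold changes over the
#' supported windows of each chromosome, for one clone. Chromosomes with
#' fewer than two supported windows get `NA` statistics.
#'
#' @param fc an `fc_track`.
#' @return data.frame with columns `clone_id`, `chrom`, `n_windows`,
#'   `mean_log2fc`, `var_log2fc`.
#' @export
intra_clone_stats <- function(fc) {
  stopifnot(inherits(fc, "fc_track"))
  layout <- fc$layout
  ci <- .window_chrom_index(layout)
  ct <- layout$chromosomes
  use <- fc$supported & is.finite(fc$log2fc)
  out <- data.frame(clone_id = fc$clone_id, chrom = ct$name,
                    n_windows = 0L, mean_log2fc = NA_real_,
                    var_log2fc = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(ct))) {
    x <- fc$log2fc[use & ci == k]
    out$n_windows[k] <- length(x)
    if (length(x) >= 1) out$mean_log2fc[k] <- mean(x)
    if (length(x) >= 2) out$var_log2fc[k] <- stats::var(x)
  }
  out
}

#' Per-window inter-clone fold-change variance
#'
#' At each window, the unbiased variance of log2 fold changes across the
#' eligible clones. A clone is eligible in a window iff its fold change is
#' defined and supported there and its copy number exceeds `min_cn`
#' (default 0.3). Windows with fewer than two eligible clones are skipped
#' (`NA`).
#'
#' @param fcs list of `fc_track`s, one per clone.
#' @param cns optional list of matching `cn_profile`s enforcing the
#'   copy-number eligibility rule; when omitted only support/definedness
#'   is required.
#' @param min_cn copy-number eligibility threshold (strict >).
#' @return list with `variance` (per window, `NA` where skipped) and
#'   `n_clones` (eligible clones per window).
#' @export
inter_clone_variance <- function(fcs, cns = NULL, min_cn = 0.3) {
  stopifnot(length(fcs) >= 2)
  layout <- fcs[[1]]$layout
  for (f in fcs) .check_same_layout(layout, f$layout, "fold-change tracks")
  n <- layout$n_windows
  k <- length(fcs)
  x <- matrix(NA_real_, nrow = n, ncol = k)
  for (j in seq_len(k)) {
    f <- fcs[[j]]
    elig <- f$supported & is.finite(f$log2fc)
    if (!is.null(cns)) {
      cnj <- cns[[j]]
      .check_same_layout(layout, cnj$layout, "fold-change and cn tracks")
      elig <- elig & !is.na(cnj$cn) & cnj$cn > min_cn
    }
    x[elig, j] <- f$log2fc[elig]
  }
  n_clones <- rowSums(!is.na(x))
  m <- rowMeans(x, na.rm = TRUE)
  ss <- rowSums((x - m)^2, na.rm = TRUE)
  v <- ifelse(n_clones >= 2, ss / (n_clones - 1), NA_real_)
  list(variance = v, n_clones = n_clones)
}

#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two value sets. For small samples (both group
#' sizes at most 8) the null distribution of U is enumerated exactly over
#' all assignments, using midranks for ties; for larger samples the normal
#' approximation with tie correction and continuity correction is used
#' (via [stats::wilcox.test()]). When every pooled value is identical the
#' test is degenerate and returns p = 1.
#'
#' @param x,y numeric vectors (`NA` dropped).
#' @return list with `U` (statistic for the first group), `p.value`,
#'   `n_x`, `n_y`, `method`.
#' @export
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("empty group in Mann-Whitney test")
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (length(unique(pooled)) == 1)
    return(list(U = U, p.value = 1, n_x = n1, n_y = n2,
                method = "degenerate (all values tied)"))
  if (max(n1, n2) <= 8) {
    combs <- utils::combn(n1 + n2, n1)
    Us <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- 2 * min(mean(Us <= U), mean(Us >= U))
    p <- min(1, p)
    return(list(U = U, p.value = p, n_x = n1, n_y = n2,
                method = "exact enumeration"))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p.value = wt$p.value, n_x = n1, n_y = n2,
       method = "normal approximation with tie correction")
}

#' Compare chromosome groups by fold-change variance
#'
#' Two-sided Mann-Whitney U test asking whether the fold-change variance
#' on one chromosome set (typically the micronucleus-transit chromosome)
#' differs from another (typically the control autosomes). Two sampling
#' units are offered: `per_clone_chromosome` compares the per-(clone,
#' chromosome) intra-clone variances from [intra_clone_stats()];
#' `per_window` compares per-window values (e.g. inter-clone variances
#' from [inter_clone_variance()]).
#'
#' @param values for `per_clone_chromosome`: a data.frame as returned by
#'   (row-binding) [intra_clone_stats()], with columns `chrom` and the
#'   column named by `value_col`; for `per_window`: a data.frame with
#'   columns `chrom` and `value_col` (one row per window).
#' @param group_a,group_b character vectors of chromosome names; both must
#'   be non-empty and select at least one finite value.
#' @param unit sampling unit (see above).
#' @param value_col column holding the compared quantity (default
#'   `"var_log2fc"` for the per-clone unit, `"variance"` otherwise).
#' @return list with `U`, `p.value`, `n_a`, `n_b`, `unit`, `method`.
#' @export
compare_chromosome_groups <- function(values, group_a, group_b,
                                      unit = c("per_clone_chromosome",
                                               "per_window"),
                                      value_col = NULL) {
  unit <- match.arg(unit)
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("both chromosome groups must be non-empty")
  if (is.null(value_col))
    value_col <- if (unit == "per_clone_chromosome") "var_log2fc"
  else "variance"
  if (!all(c("chrom", value_col) %in% names(values)))
    stop("`values` needs columns chrom and ", value_col)
  va <- values[[value_col]][values$chrom %in% group_a]
  vb <- values[[value_col]][values$chrom %in% group_b]
  va <- va[is.finite(va)]; vb <- vb[is.finite(vb)]
  if (length(va) == 0 || length(vb) == 0)
    stop("a chromosome group selects no finite values")
  res <- mann_whitney(va, vb)
  list(U = res$U, p.value = res$p.value, n_a = res$n_x, n_b = res$n_y,
       unit = unit, method = res$method)
}

#' Spearman rank correlation between paired fold changes
#'
#' Spearman correlation (midranks for ties) between two sets of paired
#' values, typically log2 fold changes of two assays (ATAC vs a histone
#' mark) over the same windows or (clone, window) pairs. Incomplete pairs
#' are dropped; at least 3 complete pairs are required. The p-value uses
#' the exact null distribution for 30 or fewer untied pairs and the
#' t approximation otherwise (via [stats::cor.test()]).
#'
#' @param x,y paired numeric vectors.
#' @return list with `rho`, `p.value`, `n`.
#' @export
assay_fold_change_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("fewer than 3 complete pairs")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = n <= 30))
  list(rho = unname(ct$estimate), p.value = ct$p.value, n = n)
}
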