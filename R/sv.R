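#' Breakend density track
#'
#' Counts structural-variant breakends into genomic bins. By default the
#' bins are the analysis windows of the layout; a coarser `bin_size` (a
#' multiple of nothing in particular - bins are tiled per chromosome like
#' windows) may be chosen. Each breakend is assigned to the bin containing
#' its position (half-open bins, so a breakend exactly at a bin start
#' belongs to the bin beginning there). Breakends on chromosomes absent
#' from the layout or beyond a chromosome's analysed span are dropped and
#' counted in the `n_outside` attribute; conservation holds over the
#' analysed regions.
#'
#' @param breakends data.frame with columns `chrom`, `position` (0-based
#'   bp), e.g. from [read_breakends()].
#' @param layout a `genome_layout`.
#' @param bin_size bin width in bp; defaults to the layout's window size.
#' @return list of class `breakend_density` with `bins` (data.frame
#'   `chrom`, `start`, `end`), `count` (per bin), `bin_size`, `n_outside`.
#' @export
breakend_density <- function(breakends, layout, bin_size = NULL) {
  stopifnot(inherits(layout, "genome_layout"))
  if (!all(c("chrom", "position") %in% names(breakends)))
    stop("breakends need columns chrom and position")
  if (is.null(bin_size)) bin_size <- layout$window_size
  ct <- layout$chromosomes
  nb <- ceiling(ct$span / bin_size)
  off <- cumsum(c(0, nb[-length(nb)]))
  chrom <- rep(ct$name, nb)
  start <- unlist(lapply(nb, function(k) (seq_len(k) - 1) * bin_size),
                  use.names = FALSE)
  end <- pmin(start + bin_size, rep(ct$span, nb))
  ci <- match(breakends$chrom, ct$name)
  pos <- breakends$position
  inside <- !is.na(ci) & pos >= 0 & pos < ct$span[ci]
  idx <- off[ci[inside]] + pos[inside] %/% bin_size + 1
  count <- tabulate(idx, nbins = sum(nb))
  structure(list(bins = data.frame(chrom = chrom, start = start, end = end,
                                   stringsAsFactors = FALSE),
                 count = count, bin_size = bin_size,
                 n_outside = sum(!inside), layout = layout),
            class = "breakend_density")
}

#' Correlation between breakend density and accessibility variance
#'
#' Spearman rank correlation between per-bin breakend counts and a
#' per-bin accessibility-variance track (per-window inter-clone variance,
#' or a per-clone |log2 fold change| track), asking whether accessibility
#' abnormalities merely mark rearranged DNA. With no breakends at all the
#' correlation is undefined and the outcome is reported as
#' `"no_breakends"` rather than rho = 0.
#'
#' @param density a `breakend_density` whose bins are the layout windows
#'   (i.e. built with the default `bin_size`).
#' @param variance numeric per-bin vector (`NA`s dropped pairwise).
#' @return list with `outcome` (`"ok"` or `"no_breakends"`), `rho`,
#'   `p.value`, `n`.
#' @export
density_variance_correlation <- function(density, variance) {
  stopifnot(inherits(density, "breakend_density"))
  if (length(variance) != length(density$count))
    stop("variance track and density bins differ in length")
  if (all(density$count == 0))
    return(list(outcome = "no_breakends", rho = NA_real_,
                p.value = NA_real_, n = 0L))
  ok <- is.finite(variance)
  res <- assay_fold_change_correlation(density$count[ok], variance[ok])
  list(outcome = "ok", rho = res$rho, p.value = res$p.value, n = res$n)
}

#' Variance in breakend-containing bins versus all bins
#'
#' Compares the accessibility-variance values of bins containing at least
#' one breakend (optionally dilated by a flank) with the values across all
#' bins: reports both means, their ratio, and a two-sided Mann-Whitney
#' p-value. A ratio near 1 with a large p indicates that accessibility
#' abnormalities are not confined to rearranged regions.
#'
#' @param variance numeric per-bin variance values.
#' @param density a `breakend_density` on the same bins.
#' @param flank dilation of breakend bins in bp (default 0).
#' @return list with `mean_breakend`, `mean_all`, `ratio`, `p.value`,
#'   `n_breakend_bins`.
#' @export
breakend_region_variance_ratio <- function(variance, density, flank = 0) {
  stopifnot(inherits(density, "breakend_density"))
  if (length(variance) != length(density$count))
    stop("variance track and density bins differ in length")
  hit <- density$count > 0
  if (!any(hit)) stop("no breakend-containing bins")
  if (flank > 0) {
    k <- ceiling(flank / density$bin_size)
    ci <- match(density$bins$chrom, unique(density$bins$chrom))
    idx <- which(hit)
    for (d in seq_len(k)) {
      lo <- idx - d; hi <- idx + d
      ok_lo <- lo >= 1 & ci[pmax(lo, 1)] == ci[idx]
      ok_hi <- hi <= length(hit) & ci[pmin(hi, length(hit))] == ci[idx]
      hit[lo[ok_lo]] <- TRUE
      hit[hi[ok_hi]] <- TRUE
    }
  }
  vb <- variance[hit]; va <- variance
  vb <- vb[is.finite(vb)]; va <- va[is.finite(va)]
  if (length(vb) == 0) stop("no finite variance values in breakend bins")
  mw <- mann_whitney(vb, va)
  list(mean_breakend = mean(vb), mean_all = mean(va),
       ratio = mean(vb) / mean(va), p.value = mw$p.value,
       n_breakend_bins = length(vb))
}
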