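#' Assign per-window copy number from segments
#'
#' Projects a per-clone copy-number segmentation onto the layout's window
#' grid. Each window's copy number C(i) is the overlap-length-weighted mean
#' of the covering segments; windows with no segment coverage are `NA`
#' ("missing") and excluded downstream. Per segment, an explicit integer
#' `cn` call takes precedence; otherwise the fractional copy number is
#' derived from the log2 copy ratio as `C = P * 2^log2`, with P the
#' expected ploidy of the chromosome in the layout (so log2 ratio 0 on a
#' diploid chromosome gives C = 2).
#'
#' @param segments a `cn_segments` table (see [read_cn_segments()]).
#' @param layout a `genome_layout`.
#' @param clone_id sample identifier; defaults to the one attached to
#'   `segments`.
#' @return object of class `cn_profile` with per-window `$cn` (`NA` where
#'   uncovered) and a `$provenance` label (`"integer_call"`,
#'   `"log2_derived"` or `"mixed"`).
#' @export
assign_window_cn <- function(segments, layout, clone_id = NULL) {
  stopifnot(inherits(layout, "genome_layout"))
  segments <- if (inherits(segments, "cn_segments")) segments else
    cn_segments(segments)
  if (is.null(clone_id))
    clone_id <- attr(segments, "clone_id") %||% "sample"

  ct <- layout$chromosomes
  ci <- match(segments$chrom, ct$name)
  if (anyNA(ci))
    stop("segment chromosome(s) absent from layout: ",
         paste(unique(segments$chrom[is.na(ci)]), collapse = ", "))
  pl <- ct$ploidy[ci]
  cn_val <- ifelse(!is.na(segments$cn), segments$cn,
                   pl * 2^segments$log2)
  if (anyNA(cn_val))
    stop("segment(s) with neither cn nor log2 value")
  if (any(cn_val < 0)) stop("negative copy number in segments")
  used_int <- !is.na(segments$cn)
  provenance <- if (all(used_int)) "integer_call"
  else if (!any(used_int)) "log2_derived" else "mixed"

  win <- layout_windows(layout)
  win_gr <- GenomicRanges::GRanges(
    win$chrom, IRanges::IRanges(win$start + 1, win$end))
  seg_gr <- GenomicRanges::GRanges(
    segments$chrom, IRanges::IRanges(segments$start + 1, segments$end))
  hits <- GenomicRanges::findOverlaps(win_gr, seg_gr)
  ov <- GenomicRanges::pintersect(
    win_gr[S4Vectors::queryHits(hits)], seg_gr[S4Vectors::subjectHits(hits)])
  w <- GenomicRanges::width(ov)
  q <- S4Vectors::queryHits(hits)
  num <- numeric(layout$n_windows)
  den <- numeric(layout$n_windows)
  num[] <- 0; den[] <- 0
  add_num <- tapply(w * cn_val[S4Vectors::subjectHits(hits)], q, sum)
  add_den <- tapply(w, q, sum)
  ii <- as.integer(names(add_num))
  num[ii] <- add_num
  den[ii] <- add_den
  cn <- ifelse(den > 0, num / den, NA_real_)

  structure(list(clone_id = clone_id, cn = cn, provenance = provenance,
                 layout = layout),
            class = "cn_profile")
}

#' Construct a copy-number profile from a per-window vector
#'
#' @param cn numeric vector of per-window copy numbers (`NA` = missing),
#'   in canonical window order.
#' @inheritParams assign_window_cn
#' @param provenance label describing how the values were obtained.
#' @export
cn_profile <- function(cn, layout, clone_id = "sample",
                       provenance = "integer_call") {
  stopifnot(inherits(layout, "genome_layout"))
  if (length(cn) != layout$n_windows)
    stop("cn length does not match layout windows")
  if (any(cn < 0, na.rm = TRUE)) stop("copy numbers must be >= 0")
  structure(list(clone_id = clone_id, cn = as.numeric(cn),
                 provenance = provenance, layout = layout),
            class = "cn_profile")
}

#' Window retention mask
#'
#' Applies the analysis filtering rules: a window is excluded iff it
#' overlaps an excluded (unmappable) region by at least 1 bp, its copy
#' number is below 0.3 (strictly; C = 0.3 exactly is retained), or its copy
#' number is missing (no segment coverage). Windows beyond a chromosome's
#' `analysis_limit` never enter the grid in the first place. Each excluded
#' window carries a reason code.
#'
#' @param layout a `genome_layout` (its `excluded_regions` are used).
#' @param cn a `cn_profile`, or `NULL` to filter on regions only.
#' @param min_cn copy-number floor; windows with C strictly below it are
#'   dropped (default 0.3).
#' @return list with `retained` (logical per window) and `reason`
#'   (character per window: `NA` for retained, else `"unmappable"`,
#'   `"low_cn"` or `"missing_cn"`, in that precedence order).
#' @export
filter_windows <- function(layout, cn = NULL, min_cn = 0.3) {
  stopifnot(inherits(layout, "genome_layout"))
  n <- layout$n_windows
  reason <- rep(NA_character_, n)
  if (!is.null(layout$excluded_regions) &&
      nrow(layout$excluded_regions) > 0) {
    win <- layout_windows(layout)
    win_gr <- GenomicRanges::GRanges(
      win$chrom, IRanges::IRanges(win$start + 1, win$end))
    ex <- layout$excluded_regions
    ex_gr <- GenomicRanges::GRanges(
      ex$chrom, IRanges::IRanges(ex$start + 1, ex$end))
    hit <- GenomicRanges::countOverlaps(win_gr, ex_gr) > 0
    reason[hit] <- "unmappable"
  }
  if (!is.null(cn)) {
    stopifnot(inherits(cn, "cn_profile"))
    .check_same_layout(layout, cn$layout, "layout and cn profile")
    low <- !is.na(cn$cn) & cn$cn < min_cn
    reason[is.na(reason) & low] <- "low_cn"
    reason[is.na(reason) & is.na(cn$cn)] <- "missing_cn"
  }
  list(retained = is.na(reason), reason = reason)
}

#' Effective length of a chromosome
#'
#' The effective length of a chromosome is its copy-number-weighted,
#' ploidy-scaled length over the retained windows:
#' `l = sum(l_i * C_i) / P`, where `l_i` is the width of window i, `C_i`
#' its average copy number and `P` the expected ploidy. With `C = P`
#' everywhere, `l` reduces to the plain retained length.
#'
#' @param widths window widths `l_i` in bp (retained windows only).
#' @param cn per-window copy numbers `C_i` (same length).
#' @param ploidy expected ploidy P (> 0); 1 for a haploid chromosome.
#' @return effective length in bp.
#' @export
effective_length <- function(widths, cn, ploidy) {
  if (length(ploidy) != 1 || !is.finite(ploidy) || ploidy <= 0)
    stop("ploidy must be a single positive number")
  if (length(widths) != length(cn))
    stop("widths and cn differ in length")
  if (length(widths) == 0) return(0)
  sum(widths * cn) / ploidy
}

# per-chromosome effective lengths over retained windows; returns a named
# vector (one entry per layout chromosome) whose sum is L
.chromosome_effective_lengths <- function(cn, layout, retained) {
  win <- layout_windows(layout)
  wi <- win$end - win$start
  ci <- .window_chrom_index(layout)
  ct <- layout$chromosomes
  l <- numeric(nrow(ct))
  for (k in seq_len(nrow(ct))) {
    sel <- ci == k & retained
    l[k] <- effective_length(wi[sel], cn$cn[sel], ct$ploidy[k])
  }
  names(l) <- ct$name
  l
}

#' Copy-number-normalized accessibility signal
#'
#' Computes the normalized signal of a clone c in window i,
#' `S(c,i) = (T(i) / C(i)) * (L / R)`, where T(i) is the window read
#' count, C(i) the window copy number, R the total mapped reads of the
#' sample across all chromosomes, and L the sum of effective chromosome
#' lengths `l = sum(l_i * C_i) / P` over retained windows. Dividing by
#' C(i) removes DNA dosage, R removes library depth, and L makes the scale
#' comparable between samples with different karyotypes. Excluded windows
#' (see [filter_windows()]) carry `NA`; a zero count gives S = 0.
#'
#' @param track a `window_track` (supplies T and R).
#' @param cn a `cn_profile` on the same layout.
#' @param mask optional retention mask from [filter_windows()]; computed
#'   from `cn` and the layout's excluded regions when omitted.
#' @param min_cn passed to [filter_windows()] when `mask` is omitted.
#' @return object of class `signal_track` with `$signal` (per window, `NA`
#'   where excluded), `$retained`, `$reason`, and the constants `$L`, `$R`
#'   used.
#' @export
normalized_signal <- function(track, cn, mask = NULL, min_cn = 0.3) {
  stopifnot(inherits(track, "window_track"), inherits(cn, "cn_profile"))
  .check_same_layout(track$layout, cn$layout, "count track and cn profile")
  layout <- track$layout
  if (is.null(mask)) mask <- filter_windows(layout, cn, min_cn = min_cn)
  retained <- mask$retained
  if (any(retained & (is.na(cn$cn) | cn$cn < min_cn)))
    stop("mask retains windows with missing or sub-threshold copy number")
  R <- track$total_reads
  if (R <= 0) stop("total reads R must be positive")
  l <- .chromosome_effective_lengths(cn, layout, retained)
  L <- sum(l)
  s <- rep(NA_real_, layout$n_windows)
  s[retained] <- (track$counts[retained] / cn$cn[retained]) * (L / R)
  structure(list(clone_id = track$clone_id, assay = track$assay,
                 signal = s, retained = retained, reason = mask$reason,
                 L = L, R = R, effective_lengths = l, layout = layout),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat("signal_track:", x$clone_id, "/", x$assay, "-",
      sum(x$retained), "of", length(x$signal), "windows retained; L =",
      format(round(x$L), big.mark = ","), ", R =",
      format(x$R, big.mark = ","), "\n")
  invisible(x)
}

#' Per-window signal table
#'
#' Assembles the per-window quantities of one sample into a single
#' data.frame suitable for TSV export: window coordinates, raw count T,
#' copy number C, normalized signal S, retention flag and exclusion
#' reason.
#'
#' @param track a `window_track`.
#' @param cn a `cn_profile`.
#' @param signal the matching `signal_track`.
#' @return data.frame with one row per window.
#' @export
signal_table <- function(track, cn, signal) {
  .check_same_layout(track$layout, signal$layout, "track and signal")
  win <- layout_windows(track$layout)
  data.frame(win,
             count = track$counts,
             cn = cn$cn,
             signal = signal$signal,
             retained = signal$retained,
             reason = signal$reason,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
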