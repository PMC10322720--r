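#' Read a BED3 file of intervals
#'
#' Thin wrapper around [rtracklayer::import()] returning 0-based half-open
#' intervals as a data.frame.
#'
#' @param path path to a BED file (at least 3 columns).
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e)
                   stop("malformed BED file '", path, "': ",
                        conditionMessage(e), call. = FALSE))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Construct a window-count track
#'
#' A `window_track` holds per-window read counts T(i) for one sample and one
#' assay, aligned to the canonical window grid of a layout, together with
#' the total mapped read count R used for depth normalization. R defaults to
#' the sum of counts across all chromosomes; pass `total_reads` when a
#' different library total (e.g. including reads in regions later filtered)
#' is known.
#'
#' @param counts numeric vector of non-negative counts, one per layout
#'   window, in canonical window order.
#' @param layout a `genome_layout`.
#' @param clone_id sample identifier (the parental line is just another
#'   sample, conventionally `"parental"`).
#' @param assay assay label, e.g. `"ATAC"`, `"H3K4me3"`, `"H3K27me3"`,
#'   `"H3K27ac"`.
#' @param total_reads optional explicit total mapped reads R.
#' @param unassigned number of input records that fell outside the layout
#'   (see [count_fragments()]); informational.
#' @return object of class `window_track`.
#' @export
window_track <- function(counts, layout, clone_id = "sample",
                         assay = "ATAC", total_reads = NULL,
                         unassigned = 0) {
  stopifnot(inherits(layout, "genome_layout"))
  if (length(counts) != layout$n_windows)
    stop("counts length (", length(counts), ") != number of layout windows (",
         layout$n_windows, ")")
  if (any(!is.finite(counts) | counts < 0))
    stop("counts must be finite and non-negative")
  if (is.null(total_reads)) total_reads <- sum(counts)
  if (total_reads <= 0) stop("total_reads must be positive")
  structure(list(clone_id = clone_id, assay = assay,
                 counts = as.numeric(counts),
                 total_reads = as.numeric(total_reads),
                 unassigned = unassigned, layout = layout),
            class = "window_track")
}

#' @export
print.window_track <- function(x, ...) {
  cat("window_track:", x$clone_id, "/", x$assay, "-",
      length(x$counts), "windows, R =", format(x$total_reads, big.mark = ","),
      "\n")
  invisible(x)
}

#' Read per-window counts from a TSV file
#'
#' Expects a header line with columns `chrom`, `start`, `end`, `count`
#' (0-based half-open windows). Every row must sit exactly on the layout's
#' window grid; windows absent from the file get count 0.
#'
#' @param path TSV path.
#' @inheritParams window_track
#' @return a `window_track` with R equal to the column sum unless
#'   `total_reads` is given.
#' @export
read_window_counts <- function(path, layout, clone_id = "sample",
                               assay = "ATAC", total_reads = NULL) {
  stopifnot(inherits(layout, "genome_layout"))
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "count")
  if (!all(need %in% names(tab)))
    stop("window count file needs columns chrom, start, end, count")
  unknown <- setdiff(unique(tab$chrom), layout$chromosomes$name)
  if (length(unknown))
    stop("count file contains chromosome(s) absent from layout: ",
         paste(unknown, collapse = ", "))
  if (any(tab$count < 0)) stop("negative counts in ", path)
  idx <- .window_index(layout, tab$chrom, tab$start)
  if (anyNA(idx))
    stop("window(s) not on the layout grid, e.g. ",
         tab$chrom[is.na(idx)][1], ":", tab$start[is.na(idx)][1])
  win <- layout_windows(layout)
  if (any(tab$end != win$end[idx]))
    stop("window end(s) do not match the layout grid")
  if (anyDuplicated(idx)) stop("duplicate windows in ", path)
  counts <- numeric(layout$n_windows)
  counts[idx] <- tab$count
  window_track(counts, layout, clone_id = clone_id, assay = assay,
               total_reads = total_reads)
}

#' Write per-window counts to a TSV file
#'
#' Inverse of [read_window_counts()]; the round trip is exact.
#'
#' @param track a `window_track`.
#' @param path output path.
#' @export
write_window_counts <- function(track, path) {
  stopifnot(inherits(track, "window_track"))
  win <- layout_windows(track$layout)
  win$count <- track$counts
  utils::write.table(win, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Count fragments into layout windows
#'
#' Each fragment is assigned to exactly one window: the window containing
#' its midpoint `floor((start + end) / 2)`. The midpoint rule guarantees
#' conservation (no fragment is counted twice even when it straddles a
#' window boundary) and determinism. Fragments on chromosomes absent from
#' the layout, or with midpoints beyond a chromosome's analysed span, are
#' tallied as `unassigned` rather than silently dropped, so
#' `sum(counts) + unassigned == number of input fragments`.
#'
#' @param fragments a BED path, a `GRanges`, or a data.frame with columns
#'   `chrom`, `start`, `end` (0-based half-open).
#' @inheritParams window_track
#' @return a `window_track`; the unassigned tally is in `$unassigned`.
#' @export
count_fragments <- function(fragments, layout, clone_id = "sample",
                            assay = "ATAC") {
  stopifnot(inherits(layout, "genome_layout"))
  if (is.character(fragments)) fragments <- read_bed(fragments)
  if (methods::is(fragments, "GRanges"))
    fragments <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(fragments)),
      start = GenomicRanges::start(fragments) - 1,
      end = GenomicRanges::end(fragments))
  if (!all(c("chrom", "start", "end") %in% names(fragments)))
    stop("fragments need columns chrom, start, end (or a BED file)")
  if (any(fragments$end <= fragments$start))
    stop("malformed fragment interval(s): end <= start")
  mid <- (fragments$start + fragments$end) %/% 2
  ct <- layout$chromosomes
  ci <- match(fragments$chrom, ct$name)
  in_span <- !is.na(ci) & mid >= 0 & mid < ct$span[ci]
  idx <- ct$offset[ci[in_span]] + mid[in_span] %/% layout$window_size + 1
  counts <- tabulate(idx, nbins = layout$n_windows)
  window_track(counts, layout, clone_id = clone_id, assay = assay,
               unassigned = sum(!in_span))
}

#' Read copy-number segments from a TSV file
#'
#' Accepts CNVKit-`.cns`-style tables: a header with columns `chromosome`
#' (or `chrom`), `start`, `end` and at least one of `log2` (log2 copy
#' ratio) and `cn` (integer copy-number call). Segments are 0-based
#' half-open and must not overlap within a chromosome. Both representations
#' are preserved when present; the precedence rule (integer call wins,
#' otherwise fractional CN derived from the log2 ratio) is applied later by
#' [assign_window_cn()].
#'
#' @param path TSV path.
#' @param clone_id sample identifier attached to the table.
#' @return data.frame of class `cn_segments` with columns `chrom`, `start`,
#'   `end`, `log2`, `cn` (either of the last two may be all-`NA`).
#' @export
read_cn_segments <- function(path, clone_id = "sample") {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  if ("chromosome" %in% names(tab) && !"chrom" %in% names(tab))
    names(tab)[names(tab) == "chromosome"] <- "chrom"
  if (!all(c("chrom", "start", "end") %in% names(tab)))
    stop("segment file needs columns chromosome (or chrom), start, end")
  if (!"log2" %in% names(tab)) tab$log2 <- NA_real_
  if (!"cn" %in% names(tab)) tab$cn <- NA_real_
  if (all(is.na(tab$log2)) && all(is.na(tab$cn)))
    stop("segment file carries neither a log2 ratio nor a cn column")
  if (any(tab$end <= tab$start))
    stop("segments must be half-open with end > start")
  cn_segments(tab[, c("chrom", "start", "end", "log2", "cn")],
              clone_id = clone_id)
}

#' @rdname read_cn_segments
#' @param segments data.frame with columns `chrom`, `start`, `end` and
#'   `log2` and/or `cn`.
#' @export
cn_segments <- function(segments, clone_id = "sample") {
  segments <- as.data.frame(segments)
  if (!"log2" %in% names(segments)) segments$log2 <- NA_real_
  if (!"cn" %in% names(segments)) segments$cn <- NA_real_
  segments$chrom <- as.character(segments$chrom)
  ord <- order(segments$chrom, segments$start)
  segments <- segments[ord, , drop = FALSE]
  by_chr <- split(segments, segments$chrom)
  for (s in by_chr) {
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
      stop("overlapping segments on ", s$chrom[1])
  }
  rownames(segments) <- NULL
  attr(segments, "clone_id") <- clone_id
  class(segments) <- c("cn_segments", "data.frame")
  segments
}

#' Write a per-window track as bedGraph
#'
#' Writes the retained windows of a signal or fold-change track (or any
#' per-window numeric vector) as a four-column bedGraph. Windows whose value
#' is undefined (excluded by filtering, unsupported, or `NA`) are omitted,
#' not written as 0, so genome-browser views do not conflate "filtered"
#' with "closed chromatin".
#'
#' @param track a `signal_track`, `fc_track`, or a plain numeric vector
#'   (then `layout` must be given); `NA` entries are skipped.
#' @param path output path.
#' @param layout required when `track` is a bare numeric vector.
#' @param value which field to write for an `fc_track`: `"log2fc"`
#'   (default) or `"fc"`.
#' @return the path, invisibly. Values round-trip through
#'   [read_bedgraph()] to at least 6 decimal places.
#' @export
write_signal_bedgraph <- function(track, path, layout = NULL,
                                  value = c("log2fc", "fc")) {
  value <- match.arg(value)
  if (inherits(track, "signal_track")) {
    v <- track$signal
    layout <- track$layout
  } else if (inherits(track, "fc_track")) {
    v <- track[[value]]
    layout <- track$layout
  } else if (is.numeric(track)) {
    if (is.null(layout)) stop("layout required for a bare numeric track")
    if (length(track) != layout$n_windows)
      stop("track length does not match layout windows")
    v <- track
  } else stop("unsupported track type")
  win <- layout_windows(layout)
  keep <- !is.na(v)
  gr <- GenomicRanges::GRanges(
    seqnames = win$chrom[keep],
    ranges = IRanges::IRanges(start = win$start[keep] + 1,
                              end = win$end[keep]),
    score = v[keep])
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph file onto a layout's window grid
#'
#' @param path bedGraph path.
#' @param layout a `genome_layout`.
#' @return numeric vector in canonical window order; windows absent from
#'   the file are `NA`.
#' @export
read_bedgraph <- function(path, layout) {
  stopifnot(inherits(layout, "genome_layout"))
  gr <- rtracklayer::import(path, format = "bedGraph")
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start <- GenomicRanges::start(gr) - 1
  idx <- .window_index(layout, chrom, start)
  if (anyNA(idx))
    stop("bedGraph interval(s) not on the layout grid in ", path)
  v <- rep(NA_real_, layout$n_windows)
  v[idx] <- gr$score
  v
}

#' Read structural-variant breakends
#'
#' Accepts either a two-column TSV with header `chrom`, `position`
#' (additional columns such as `clone` are kept), or a headerless BEDPE
#' file, in which case both junction sides (`chrom1:start1`, and
#' `chrom2:start2` where `chrom2 != "."`) are returned as breakends.
#'
#' @param path input path.
#' @return data.frame of class `breakend_set` with columns `chrom`,
#'   `position` (0-based bp).
#' @export
read_breakends <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("chrom", first) && grepl("position", first)) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    out <- tab[, c("chrom", "position",
                   intersect("clone", names(tab))), drop = FALSE]
  } else {
    tab <- utils::read.table(path, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 6)
      stop("breakend file is neither a chrom/position TSV nor BEDPE: ", path)
    a <- data.frame(chrom = as.character(tab[[1]]),
                    position = as.numeric(tab[[2]]))
    b <- data.frame(chrom = as.character(tab[[4]]),
                    position = as.numeric(tab[[5]]))
    out <- rbind(a, b[b$chrom != ".", , drop = FALSE])
  }
  rownames(out) <- NULL
  class(out) <- c("breakend_set", "data.frame")
  out
}

#' Write / read a synthetic-truth table
#'
#' The ground truth of a simulated cohort (latent log perturbations per
#' clone, window and assay, plus the copy-number truth) round-trips through
#' a plain TSV so recovery analyses can run from files alone.
#'
#' @param truth data.frame as found in the `$truth` element of a simulated
#'   cohort.
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
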