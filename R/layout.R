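#' Construct a genome layout
#'
#' A `genome_layout` fixes the coordinate frame shared by every downstream
#' object: the ordered set of chromosomes, their expected ploidies, the
#' analysis window grid, and any regions excluded from analysis (typically
#' unmappable regions). All coordinates in this package are 0-based,
#' half-open (BED convention).
#'
#' Windows are tiled per chromosome from position 0 in steps of
#' `window_size`; the last window of a chromosome is kept and clipped to the
#' chromosome length (or to `analysis_limit` where set). `analysis_limit`
#' truncates the analysed span of a chromosome, e.g. a Y chromosome analysed
#' only up to 26.68 Mbp because no confidently aligned reads exist beyond it.
#'
#' @param chromosomes data.frame with columns `name`, `length` (bp),
#'   `ploidy` (expected copy number of the chromosome in the parental
#'   karyotype; 1 for a haploid chromosome such as the Y, 2 otherwise) and
#'   optionally `analysis_limit` (bp, `NA` for none).
#' @param window_size analysis window size in bp (default 10000).
#' @param excluded_regions optional data.frame with columns `chrom`,
#'   `start`, `end` (0-based half-open) of regions to exclude, or a path to
#'   a BED3 file.
#' @param allow_nonstandard_ploidy if `FALSE` (default) ploidies outside
#'   `{1, 2}` are rejected; set `TRUE` to permit arbitrary positive values.
#' @return An object of class `genome_layout`.
#' @examples
#' layout <- genome_layout(
#'   data.frame(name = c("chr1", "chrY"), length = c(5e7, 5.7e7),
#'              ploidy = c(2, 1), analysis_limit = c(NA, 26680000)))
#' layout
#' @export
genome_layout <- function(chromosomes, window_size = 10000,
                          excluded_regions = NULL,
                          allow_nonstandard_ploidy = FALSE) {
  if (!is.data.frame(chromosomes) || nrow(chromosomes) == 0)
    stop("`chromosomes` must be a non-empty data.frame")
  need <- c("name", "length", "ploidy")
  miss <- setdiff(need, names(chromosomes))
  if (length(miss))
    stop("`chromosomes` lacks column(s): ", paste(miss, collapse = ", "))
  chromosomes$name <- as.character(chromosomes$name)
  if (anyDuplicated(chromosomes$name))
    stop("duplicate chromosome name(s): ",
         paste(unique(chromosomes$name[duplicated(chromosomes$name)]),
               collapse = ", "))
  if (any(!is.finite(chromosomes$length) | chromosomes$length <= 0))
    stop("all chromosome lengths must be positive")
  if (any(!is.finite(chromosomes$ploidy) | chromosomes$ploidy <= 0))
    stop("all ploidies must be positive")
  if (!allow_nonstandard_ploidy && !all(chromosomes$ploidy %in% c(1, 2)))
    stop("expected ploidy must be 1 or 2 ",
         "(use allow_nonstandard_ploidy = TRUE to override)")
  if (is.null(chromosomes$analysis_limit))
    chromosomes$analysis_limit <- NA_real_
  bad <- !is.na(chromosomes$analysis_limit) &
    (chromosomes$analysis_limit <= 0 |
       chromosomes$analysis_limit > chromosomes$length)
  if (any(bad))
    stop("analysis_limit must lie in (0, chromosome length]: ",
         paste(chromosomes$name[bad], collapse = ", "))
  if (!is.numeric(window_size) || length(window_size) != 1 || window_size <= 0)
    stop("`window_size` must be a single positive number")

  if (is.character(excluded_regions))
    excluded_regions <- read_bed(excluded_regions)
  if (!is.null(excluded_regions)) {
    if (!all(c("chrom", "start", "end") %in% names(excluded_regions)))
      stop("excluded_regions needs columns chrom, start, end")
    excluded_regions <- data.frame(
      chrom = as.character(excluded_regions$chrom),
      start = as.numeric(excluded_regions$start),
      end = as.numeric(excluded_regions$end))
    if (any(excluded_regions$end <= excluded_regions$start))
      stop("excluded_regions must be half-open intervals with end > start")
  }

  span <- ifelse(is.na(chromosomes$analysis_limit),
                 chromosomes$length, chromosomes$analysis_limit)
  n_windows <- ceiling(span / window_size)
  chrom_tab <- data.frame(
    name = chromosomes$name,
    length = as.numeric(chromosomes$length),
    ploidy = as.numeric(chromosomes$ploidy),
    analysis_limit = as.numeric(chromosomes$analysis_limit),
    span = as.numeric(span),
    n_windows = as.integer(n_windows),
    offset = as.integer(cumsum(c(0, n_windows[-length(n_windows)]))),
    stringsAsFactors = FALSE)

  structure(list(chromosomes = chrom_tab,
                 window_size = as.numeric(window_size),
                 excluded_regions = excluded_regions,
                 n_windows = sum(chrom_tab$n_windows)),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", nrow(x$chromosomes), "chromosome(s),",
      x$n_windows, "windows of", format(x$window_size, big.mark = ","),
      "bp\n")
  print(x$chromosomes[, c("name", "length", "ploidy", "analysis_limit",
                          "n_windows")], row.names = FALSE)
  if (!is.null(x$excluded_regions))
    cat(nrow(x$excluded_regions), "excluded region(s)\n")
  invisible(x)
}

#' Window grid of a layout
#'
#' Deterministically derives the analysis windows of a layout, in chromosome
#' order then coordinate order. The last window of each chromosome is
#' clipped to the chromosome span.
#'
#' @param layout a `genome_layout`.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), one row per window, in the canonical order used by all
#'   per-window vectors in the package.
#' @export
layout_windows <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  ct <- layout$chromosomes
  ws <- layout$window_size
  chrom <- rep(ct$name, ct$n_windows)
  start <- unlist(lapply(ct$n_windows, function(k) (seq_len(k) - 1) * ws),
                  use.names = FALSE)
  end <- start + ws
  end <- pmin(end, rep(ct$span, ct$n_windows))
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Read a genome layout from a TSV or YAML file
#'
#' TSV files need a header with columns `name` (or `chrom`), `length`,
#' `ploidy` and optionally `analysis_limit`. YAML files may carry
#' `window_size`, a `chromosomes` list (each entry with `name`, `length`,
#' `ploidy`, optional `analysis_limit`), and an `excluded_regions` list
#' (each entry with `chrom`, `start`, `end`). Coordinates are 0-based,
#' half-open.
#'
#' @param path file path; `.yaml`/`.yml` is parsed as YAML, anything else
#'   as tab-separated text.
#' @param window_size window size in bp; ignored when the YAML file sets
#'   its own.
#' @param excluded_regions optional BED3 path or data.frame, merged with any
#'   regions named in a YAML file.
#' @inheritParams genome_layout
#' @return a `genome_layout`.
#' @export
read_genome_layout <- function(path, window_size = 10000,
                               excluded_regions = NULL,
                               allow_nonstandard_ploidy = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg$chromosomes) || length(cfg$chromosomes) == 0)
      stop("layout file defines no chromosomes: ", path)
    chroms <- do.call(rbind, lapply(cfg$chromosomes, function(ch) {
      data.frame(name = as.character(ch$name),
                 length = as.numeric(ch$length),
                 ploidy = as.numeric(ch$ploidy),
                 analysis_limit = if (is.null(ch$analysis_limit))
                   NA_real_ else as.numeric(ch$analysis_limit),
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(cfg$window_size)) window_size <- as.numeric(cfg$window_size)
    excl <- NULL
    if (!is.null(cfg$excluded_regions) && length(cfg$excluded_regions))
      excl <- do.call(rbind, lapply(cfg$excluded_regions, function(r)
        data.frame(chrom = as.character(r$chrom), start = as.numeric(r$start),
                   end = as.numeric(r$end), stringsAsFactors = FALSE)))
    if (!is.null(excluded_regions)) {
      if (is.character(excluded_regions))
        excluded_regions <- read_bed(excluded_regions)
      excl <- rbind(excl, excluded_regions[, c("chrom", "start", "end")])
    }
    return(genome_layout(chroms, window_size = window_size,
                         excluded_regions = excl,
                         allow_nonstandard_ploidy = allow_nonstandard_ploidy))
  }
  if (file.size(path) == 0) stop("layout file is empty: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           blank.lines.skip = TRUE)
  if (nrow(tab) == 0) stop("layout file lists no chromosomes: ", path)
  names(tab) <- tolower(names(tab))
  if ("chrom" %in% names(tab) && !"name" %in% names(tab))
    names(tab)[names(tab) == "chrom"] <- "name"
  if (!all(c("name", "length", "ploidy") %in% names(tab)))
    stop("layout TSV needs columns name (or chrom), length, ploidy")
  if (is.character(tab$ploidy)) {
    pl <- suppressWarnings(as.numeric(tab$ploidy))
    if (anyNA(pl))
      stop("unknown ploidy token(s): ",
           paste(unique(tab$ploidy[is.na(pl)]), collapse = ", "))
    tab$ploidy <- pl
  }
  genome_layout(tab, window_size = window_size,
                excluded_regions = excluded_regions,
                allow_nonstandard_ploidy = allow_nonstandard_ploidy)
}

# map (chrom, start) pairs to canonical window row indices; NA where the
# chromosome is unknown or the start is off-grid / beyond the analysed span
.window_index <- function(layout, chrom, start) {
  ct <- layout$chromosomes
  ci <- match(chrom, ct$name)
  ws <- layout$window_size
  idx <- ct$offset[ci] + start %/% ws + 1
  ok <- !is.na(ci) & start >= 0 & start %% ws == 0 &
    start < ct$span[ci]
  idx[!ok] <- NA_integer_
  as.integer(idx)
}

# per-window chromosome index (into layout$chromosomes) for fast grouping
.window_chrom_index <- function(layout) {
  rep(seq_len(nrow(layout$chromosomes)), layout$chromosomes$n_windows)
}

.check_same_layout <- function(a, b, what = "objects") {
  if (!identical(a, b))
    stop(what, " are not on the same genome layout / window grid")
  invisible(TRUE)
}
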