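Package: mnaccess
Title: Clone-Resolved, Copy-Number-Normalized Chromatin Accessibility Variance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies heritable epigenetic dysregulation on chromosomes that
    transited through a micronucleus. Computes copy-number-, depth- and
    genome-length-normalized accessibility signal per genomic window for
    ATAC-seq and CUT&RUN window counts, clone-versus-parental log2 fold
    changes, intra-clone (per chromosome) and inter-clone (per window)
    fold-change variance, Mann-Whitney comparisons of a designated transit
    chromosome against control autosomes, Spearman coupling of fold changes
    between assays, and association of accessibility variance with
    structural-variant breakend density. Includes a negative-binomial
    synthetic cohort generator (parental line plus single-cell clones with
    clone-private, direction-random perturbations confined to the transit
    chromosome) with full ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    methods,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
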