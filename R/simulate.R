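#' Default simulated genome layout
#'
#' Four diploid autosome-like chromosomes of 50 Mb plus one haploid
#' transit chromosome of 57 Mb analysed only up to 26.68 Mb, tiled in
#' 10-kb windows - the karyotype shape of a male near-diploid line whose Y
#' chromosome was forced through a micronucleus.
#'
#' @param window_size window size in bp.
#' @return a `genome_layout`.
#' @export
default_sim_layout <- function(window_size = 10000) {
  genome_layout(data.frame(
    name = c("chr1", "chr2", "chr3", "chr4", "chrY"),
    length = c(5e7, 5e7, 5e7, 5e7, 5.7e7),
    ploidy = c(2, 2, 2, 2, 1),
    analysis_limit = c(NA, NA, NA, NA, 26680000)),
    window_size = window_size)
}

#' Simulation configuration
#'
#' Parameters of the synthetic cohort generator. The defaults encode the
#' study design the analysis targets: 14 single-cell clones plus one
#' parental line, 10-kb windows, one haploid transit chromosome, and
#' clone-private accessibility perturbations with no consistent direction.
#'
#' @param layout a `genome_layout`; see [default_sim_layout()].
#' @param n_clones number of single-cell clones (default 14).
#' @param depth expected reads per window at neutral copy number
#'   (default 500).
#' @param nb_dispersion negative-binomial dispersion phi
#'   (`variance = mu + phi * mu^2`); 0 gives Poisson counts
#'   (default 0.05).
#' @param perturb_fraction fraction f of transit-chromosome windows
#'   perturbed per clone (default 0.2).
#' @param perturb_magnitude perturbation magnitude delta on the
#'   natural-log scale (default `log(2)`, i.e. a twofold change).
#' @param assay_coupling latent correlation rho between the ATAC
#'   perturbation and the histone-mark perturbation (default 0.35).
#' @param baseline_sd standard deviation sigma0 of the per-window
#'   log-normal baseline accessibility; its mean is set to
#'   `-sigma0^2 / 2` so the expected multiplicative baseline is 1
#'   (default 0.5).
#' @param transit_chrom name of the transit chromosome (default
#'   `"chrY"`).
#' @param cn_events list of clone-private copy-number events, each a list
#'   with `clone` (1-based clone index), `chrom`, `start`, `end`, `cn`.
#' @param breakend_rate expected number of breakends per clone
#'   (Poisson; default 50).
#' @param breakend_coupling probability that a breakend is placed inside
#'   a perturbed window of its clone instead of uniformly (default 0:
#'   placement independent of perturbations).
#' @param assays assay labels to simulate; the first is the ATAC-like
#'   anchor assay, any second one is the coupled histone mark.
#' @param effect_model `"two_point"` (u = +/- delta with equal sign
#'   probability; directly encodes direction-random effects) or
#'   `"gaussian"` (u ~ Normal(0, delta^2)).
#' @param seed RNG seed; a fixed seed makes the cohort byte-identical
#'   across runs.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(layout = default_sim_layout(), n_clones = 14,
                       depth = 500, nb_dispersion = 0.05,
                       perturb_fraction = 0.2,
                       perturb_magnitude = log(2),
                       assay_coupling = 0.35, baseline_sd = 0.5,
                       transit_chrom = "chrY", cn_events = list(),
                       breakend_rate = 50, breakend_coupling = 0,
                       assays = c("ATAC", "H3K27ac"),
                       effect_model = c("two_point", "gaussian"),
                       seed = 1) {
  effect_model <- match.arg(effect_model)
  stopifnot(inherits(layout, "genome_layout"))
  if (!transit_chrom %in% layout$chromosomes$name)
    stop("transit_chrom '", transit_chrom, "' is not in the layout")
  if (n_clones < 1) stop("n_clones must be >= 1")
  if (depth <= 0) stop("depth must be positive")
  if (nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (perturb_fraction < 0 || perturb_fraction > 1)
    stop("perturb_fraction must lie in [0, 1]")
  if (perturb_magnitude < 0) stop("perturb_magnitude must be >= 0")
  if (abs(assay_coupling) > 1)
    stop("assay_coupling must lie in [-1, 1]")
  if (breakend_coupling < 0 || breakend_coupling > 1)
    stop("breakend_coupling must lie in [0, 1]")
  if (breakend_rate < 0) stop("breakend_rate must be >= 0")
  for (ev in cn_events)
    if (!all(c("clone", "chrom", "start", "end", "cn") %in% names(ev)))
      stop("each cn_event needs fields clone, chrom, start, end, cn")
  structure(list(layout = layout, n_clones = as.integer(n_clones),
                 depth = depth, nb_dispersion = nb_dispersion,
                 perturb_fraction = perturb_fraction,
                 perturb_magnitude = perturb_magnitude,
                 assay_coupling = assay_coupling,
                 baseline_sd = baseline_sd,
                 transit_chrom = transit_chrom, cn_events = cn_events,
                 breakend_rate = breakend_rate,
                 breakend_coupling = breakend_coupling,
                 assays = assays, effect_model = effect_model,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# draw counts with NB(mu, phi) parameterisation, Poisson at phi = 0
.rcounts <- function(n, mu, phi) {
  if (phi == 0) stats::rpois(n, mu)
  else stats::rnbinom(n, mu = mu, size = 1 / phi)
}

# clone-private latent perturbation on the transit windows:
# two-point +/- delta with probability f, else 0 (or gaussian variant)
.draw_perturbation <- function(n, f, delta, model) {
  hit <- stats::runif(n) < f
  u <- numeric(n)
  if (model == "two_point") {
    u[hit] <- delta * sign(stats::runif(sum(hit)) - 0.5)
    u[hit][u[hit] == 0] <- delta   # runif == 0.5 has probability 0
  } else {
    u[hit] <- stats::rnorm(sum(hit), 0, delta)
  }
  u
}

#' Simulate a parental line plus clones
#'
#' Generates window-count tracks for a parental line and `n_clones`
#' single-cell clones across one or two assays, with full ground truth.
#' The generative model per window i and clone c is:
#' a shared multiplicative baseline `exp(lambda_i)` with
#' `lambda_i ~ Normal(-sigma0^2/2, sigma0^2)` (log-normal baseline, unit
#' mean); a clone-private latent log perturbation `u(c,i)` that is nonzero
#' only on the transit chromosome, where each window is independently
#' perturbed with probability f by `+/- delta` with equal sign
#' probability; counts
#' `T(c,i) ~ NB(mean = depth * (C(c,i)/P) * exp(lambda_i + u(c,i)),
#' dispersion phi)`. A second assay shares the anchor assay's perturbed
#' loci: there, `u_mark = rho * u_atac + sqrt(1 - rho^2) * eps`, with
#' `eps` an independent effect of the same magnitude distribution
#' (`+/- delta`), so dysregulated regions coincide across assays while
#' `rho` controls how strongly the effects co-vary. The parental line has
#' `u == 0` and
#' neutral copy number. Copy-number events scale expected counts through
#' `C/P`, so copy-number normalization should remove them. Breakends are
#' placed uniformly over the analysed genome, or with probability
#' `breakend_coupling` inside the clone's perturbed windows.
#'
#' @param config a `sim_config`.
#' @return list of class `mn_cohort` with elements `layout`, `config`,
#'   `tracks` (`$parental` and `$clones`, each a list per assay of
#'   `window_track`s), `cn` (`$parental`, `$clones`: `cn_profile`s),
#'   `breakends` (data.frame `clone`, `chrom`, `position`), and `truth`
#'   (data.frame `clone`, `chrom`, `start`, `end`, `cn`, one latent `u_*`
#'   column per assay).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed, kind = "Mersenne-Twister")

  layout <- config$layout
  win <- layout_windows(layout)
  n <- layout$n_windows
  ct <- layout$chromosomes
  ci <- .window_chrom_index(layout)
  ploidy_w <- ct$ploidy[ci]
  transit <- win$chrom == config$transit_chrom
  phi <- config$nb_dispersion
  s0 <- config$baseline_sd
  lambda <- stats::rnorm(n, -s0^2 / 2, s0)

  clone_ids <- sprintf("clone%02d", seq_len(config$n_clones))

  # copy-number truth: neutral (C = P) plus configured events
  cn_mat <- matrix(rep(ploidy_w, config$n_clones), nrow = n)
  for (ev in config$cn_events) {
    j <- ev$clone
    if (j < 1 || j > config$n_clones)
      stop("cn_event clone index out of range: ", j)
    sel <- win$chrom == ev$chrom & win$start >= ev$start &
      win$start < ev$end
    cn_mat[sel, j] <- ev$cn
  }

  n_assays <- length(config$assays)
  u <- vector("list", n_assays)        # n x n_clones latent matrices
  names(u) <- config$assays
  f <- config$perturb_fraction
  delta <- config$perturb_magnitude
  rho <- config$assay_coupling
  nt <- sum(transit)
  u_anchor <- matrix(0, n, config$n_clones)
  for (j in seq_len(config$n_clones))
    u_anchor[transit, j] <- .draw_perturbation(nt, f, delta,
                                               config$effect_model)
  u[[1]] <- u_anchor
  if (n_assays >= 2) {
    # coupled assays share the anchor's perturbed loci: at each hit
    # window, u_mark = rho * u_atac + sqrt(1 - rho^2) * eps with eps an
    # independent effect of the same magnitude distribution (+/- delta,
    # or Normal(0, delta^2) in the gaussian model)
    for (a in 2:n_assays) {
      um <- matrix(0, n, config$n_clones)
      for (j in seq_len(config$n_clones)) {
        ua <- u_anchor[transit, j]
        hit <- ua != 0
        eps <- numeric(nt)
        if (config$effect_model == "two_point") {
          eps[hit] <- delta * sign(stats::runif(sum(hit)) - 0.5)
          eps[hit][eps[hit] == 0] <- delta
        } else {
          eps[hit] <- stats::rnorm(sum(hit), 0, delta)
        }
        um[transit, j] <- rho * ua + sqrt(1 - rho^2) * eps
      }
      u[[a]] <- um
    }
  }

  base_mu <- config$depth * exp(lambda)
  parental <- lapply(config$assays, function(a)
    window_track(.rcounts(n, base_mu, phi), layout,
                 clone_id = "parental", assay = a))
  names(parental) <- config$assays
  clones <- lapply(seq_len(config$n_clones), function(j) {
    dose <- cn_mat[, j] / ploidy_w
    tr <- lapply(config$assays, function(a)
      window_track(.rcounts(n, base_mu * dose * exp(u[[a]][, j]), phi),
                   layout, clone_id = clone_ids[j], assay = a))
    names(tr) <- config$assays
    tr
  })
  names(clones) <- clone_ids

  cn_parental <- cn_profile(ploidy_w, layout, clone_id = "parental")
  cn_clones <- lapply(seq_len(config$n_clones), function(j)
    cn_profile(cn_mat[, j], layout, clone_id = clone_ids[j]))
  names(cn_clones) <- clone_ids

  # breakend placement: uniform over analysed genome, or inside the
  # clone's perturbed windows with probability breakend_coupling
  spans <- ct$span
  genome_bp <- sum(spans)
  bk <- list()
  for (j in seq_len(config$n_clones)) {
    nb <- stats::rpois(1, config$breakend_rate)
    if (nb == 0) next
    coupled <- stats::runif(nb) < config$breakend_coupling
    pert_idx <- which(u_anchor[, j] != 0)
    pos <- numeric(nb); chr <- character(nb)
    n_unif <- sum(!coupled)
    if (n_unif > 0) {
      g <- stats::runif(n_unif, 0, genome_bp)
      kk <- findInterval(g, cumsum(spans), left.open = TRUE) + 1
      chr[!coupled] <- ct$name[kk]
      pos[!coupled] <- floor(g - c(0, cumsum(spans))[kk])
    }
    n_cp <- sum(coupled)
    if (n_cp > 0) {
      if (length(pert_idx) == 0) {
        # no perturbed windows to couple to; fall back to uniform
        g <- stats::runif(n_cp, 0, genome_bp)
        kk <- findInterval(g, cumsum(spans), left.open = TRUE) + 1
        chr[coupled] <- ct$name[kk]
        pos[coupled] <- floor(g - c(0, cumsum(spans))[kk])
      } else {
        wsel <- pert_idx[sample.int(length(pert_idx), n_cp,
                                    replace = TRUE)]
        chr[coupled] <- win$chrom[wsel]
        pos[coupled] <- win$start[wsel] +
          floor(stats::runif(n_cp) * (win$end[wsel] - win$start[wsel]))
      }
    }
    bk[[length(bk) + 1]] <- data.frame(clone = clone_ids[j], chrom = chr,
                                       position = pos,
                                       stringsAsFactors = FALSE)
  }
  breakends <- if (length(bk)) do.call(rbind, bk) else
    data.frame(clone = character(), chrom = character(),
               position = numeric(), stringsAsFactors = FALSE)
  class(breakends) <- c("breakend_set", "data.frame")

  truth <- do.call(rbind, lapply(seq_len(config$n_clones), function(j) {
    tr <- data.frame(clone = clone_ids[j], chrom = win$chrom,
                     start = win$start, end = win$end,
                     cn = cn_mat[, j], stringsAsFactors = FALSE)
    for (a in config$assays) tr[[paste0("u_", a)]] <- u[[a]][, j]
    tr
  }))
  rownames(truth) <- NULL

  structure(list(layout = layout, config = config,
                 tracks = list(parental = parental, clones = clones),
                 cn = list(parental = cn_parental, clones = cn_clones),
                 breakends = breakends, truth = truth,
                 baseline_log = lambda),
            class = "mn_cohort")
}

#' @export
print.mn_cohort <- function(x, ...) {
  cat("mn_cohort:", x$config$n_clones, "clone(s) + parental,",
      length(x$config$assays), "assay(s),",
      x$layout$n_windows, "windows; transit =",
      x$config$transit_chrom, "; seed =", x$config$seed, "\n")
  invisible(x)
}

#' Run the normalization and variance pipeline on a cohort
#'
#' Convenience driver: computes the copy-number-normalized signal of the
#' parental line and each clone, clone-versus-parental fold changes with
#' the low-count support rule, per-(clone, chromosome) intra-clone
#' statistics, per-window inter-clone variance, and the transit-versus-
#' autosome Mann-Whitney group test on the chosen sampling unit.
#'
#' @param cohort an `mn_cohort` from [simulate_cohort()] (or any list with
#'   the same shape built from real data files).
#' @param assay which assay to analyse (default the cohort's first).
#' @param unit sampling unit of the group test (see
#'   [compare_chromosome_groups()]).
#' @param support_threshold read threshold of the support rule.
#' @return list of class `mn_analysis` with `signal` (list: parental +
#'   clones), `fc` (list per clone), `intra` (row-bound
#'   [intra_clone_stats()] table), `inter` (from
#'   [inter_clone_variance()]), `group_test`, `transit_chrom`, `assay`.
#' @export
analyze_cohort <- function(cohort, assay = NULL,
                           unit = c("per_window", "per_clone_chromosome"),
                           support_threshold = 200) {
  unit <- match.arg(unit)
  assay <- assay %||% cohort$config$assays[1]
  layout <- cohort$layout
  transit <- cohort$config$transit_chrom
  mask <- filter_windows(layout, cohort$cn$parental)
  sp <- normalized_signal(cohort$tracks$parental[[assay]],
                          cohort$cn$parental, mask = mask)
  tp <- cohort$tracks$parental[[assay]]
  clone_ids <- names(cohort$tracks$clones)
  sc <- list(); fc <- list()
  for (id in clone_ids) {
    cnc <- cohort$cn$clones[[id]]
    mc <- filter_windows(layout, cnc)
    sc[[id]] <- normalized_signal(cohort$tracks$clones[[id]][[assay]],
                                  cnc, mask = mc)
    fc[[id]] <- fold_change(sc[[id]], sp,
                            counts_c = cohort$tracks$clones[[id]][[assay]],
                            counts_p = tp,
                            support_threshold = support_threshold)
  }
  intra <- do.call(rbind, lapply(fc, intra_clone_stats))
  rownames(intra) <- NULL
  inter <- inter_clone_variance(fc, cns = cohort$cn$clones)
  autosomes <- setdiff(layout$chromosomes$name, transit)
  values <- if (unit == "per_clone_chromosome") intra else
    data.frame(chrom = layout_windows(layout)$chrom,
               variance = inter$variance, stringsAsFactors = FALSE)
  gt <- compare_chromosome_groups(values, group_a = transit,
                                  group_b = autosomes, unit = unit)
  structure(list(signal = c(list(parental = sp), sc), fc = fc,
                 intra = intra, inter = inter, group_test = gt,
                 transit_chrom = transit, assay = assay,
                 seed = cohort$config$seed, layout = layout),
            class = "mn_analysis")
}

#' Recovery metrics against simulation ground truth
#'
#' Measures how well the pipeline recovered what the generator planted:
#' (a) whether the transit chromosome ranks first among all chromosomes by
#' mean intra-clone log2 fold-change variance; (b) the transit-versus-
#' autosome group-test p-value; (c) the Spearman coupling between the two
#' assays' log2 fold changes on perturbed transit (clone, window) pairs,
#' next to the same Spearman computed on the latent perturbations
#' themselves and the configured coupling; (d) precision at k: the
#' fraction of truly perturbed (clone, window) pairs among the k pairs
#' with the largest |log2 fold change|, k being the number of perturbed
#' pairs.
#'
#' @param cohort the simulated `mn_cohort`.
#' @param analysis an `mn_analysis` of the anchor assay; computed when
#'   omitted.
#' @param analysis2 an `mn_analysis` of the coupled assay; computed when
#'   omitted and the cohort has a second assay.
#' @return one-row data.frame with columns `transit_rank`,
#'   `transit_rank_first`, `group_p`, `rho_est`, `rho_latent`,
#'   `rho_config`, `n_pairs`, `precision_at_k`, `k`.
#' @export
evaluate_recovery <- function(cohort, analysis = NULL, analysis2 = NULL) {
  stopifnot(inherits(cohort, "mn_cohort"))
  assays <- cohort$config$assays
  if (is.null(analysis)) analysis <- analyze_cohort(cohort, assays[1])
  if (!identical(analysis$seed, cohort$config$seed))
    stop("analysis and cohort come from different runs")
  transit <- cohort$config$transit_chrom

  mean_var <- tapply(analysis$intra$var_log2fc, analysis$intra$chrom,
                     mean, na.rm = TRUE)
  rk <- rank(-mean_var)[transit]
  group_p <- analysis$group_test$p.value

  rho_est <- rho_latent <- NA_real_
  n_pairs <- 0L
  if (length(assays) >= 2) {
    if (is.null(analysis2)) analysis2 <- analyze_cohort(cohort, assays[2])
    if (!identical(analysis2$seed, cohort$config$seed))
      stop("analysis2 and cohort come from different runs")
    u1 <- paste0("u_", assays[1]); u2 <- paste0("u_", assays[2])
    win <- layout_windows(cohort$layout)
    x1 <- c(); x2 <- c(); l1 <- c(); l2 <- c()
    for (id in names(analysis$fc)) {
      tr <- cohort$truth[cohort$truth$clone == id, ]
      pert <- tr[[u1]] != 0 & tr$chrom == transit
      f1 <- analysis$fc[[id]]; f2 <- analysis2$fc[[id]]
      ok <- pert & f1$supported & f2$supported &
        is.finite(f1$log2fc) & is.finite(f2$log2fc)
      x1 <- c(x1, f1$log2fc[ok]); x2 <- c(x2, f2$log2fc[ok])
      l1 <- c(l1, tr[[u1]][ok]); l2 <- c(l2, tr[[u2]][ok])
    }
    n_pairs <- length(x1)
    if (n_pairs >= 3) {
      rho_est <- assay_fold_change_correlation(x1, x2)$rho
      rho_latent <- assay_fold_change_correlation(l1, l2)$rho
    }
  }

  # precision@k over (clone, window) pairs ranked by |log2FC|
  u1 <- paste0("u_", assays[1])
  scores <- c(); positive <- c()
  for (id in names(analysis$fc)) {
    tr <- cohort$truth[cohort$truth$clone == id, ]
    f1 <- analysis$fc[[id]]
    ok <- f1$supported & is.finite(f1$log2fc)
    scores <- c(scores, abs(f1$log2fc[ok]))
    positive <- c(positive, tr[[u1]][ok] != 0)
  }
  k <- sum(positive)
  precision <- if (k >= 1)
    mean(positive[order(scores, decreasing = TRUE)[seq_len(k)]])
  else NA_real_

  data.frame(transit_rank = unname(rk),
             transit_rank_first = unname(rk) == 1,
             group_p = group_p,
             rho_est = rho_est, rho_latent = rho_latent,
             rho_config = cohort$config$assay_coupling,
             n_pairs = n_pairs,
             precision_at_k = precision, k = k)
}
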