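#' Analysis thresholds
#'
#' @param min_count minimum summed allele count for the polymorphism filter.
#' @param max_freq strict conditioning ceiling on the parental frequency at
#'   the adaptation endpoint.
#' @param boundary_eps clamp margin for the log-odds selection estimator;
#'   `NULL` uses `1 / (2 * coverage)`.
#' @param bins number of starting-frequency bins.
#' @param n_boot bootstrap resamples for confidence intervals.
#' @param n_perm permutations for the frequency--response correlation test.
#' @return A named list of thresholds.
#' @export
analysis_thresholds <- function(min_count = 5, max_freq = 0.9,
                                boundary_eps = NULL, bins = 10,
                                n_boot = 1000, n_perm = 1000) {
  list(min_count = min_count, max_freq = max_freq,
       boundary_eps = boundary_eps, bins = bins, n_boot = n_boot,
       n_perm = n_perm)
}

# Frequency of a polarized beneficial allele given the tracked-allele
# frequency matrix: identity when the beneficial allele is the tracked base,
# complement otherwise.
oriented_freq <- function(freq_col, tracked_base, beneficial_allele) {
  ifelse(beneficial_allele == tracked_base, freq_col, 1 - freq_col)
}

#' End-to-end analysis of an admixture experiment
#'
#' Runs the full inference chain on a simulated (or reconstructed)
#' experiment dataset: the pooled min-count polymorphism filter; per-parent
#' polarization of the rising allele over the adaptation window and
#' conditioning on presence and the frequency ceiling; per-mixture
#' selection-coefficient estimates over the F1-F20 and F20-F29 windows plus
#' the parental adaptation (0-110) and control (110-130) windows; mean
#' allele-frequency changes of the immigrant- and recipient-polarized
#' classes; the frequency-binned response with its rank correlation; the
#' cost of pleiotropy and its comparison to the realized parental
#' selection; pairwise parental FST at the time of admixture; and a PCA of
#' all samples. A filter log records every exclusion.
#'
#' @param ds an [run_experiment()] dataset (or [read_experiment_files()]
#'   bundle together with `design`).
#' @param thresholds an [analysis_thresholds()] list.
#' @param design the [experiment_design()]; defaults to `ds$design`.
#' @param coverage mean coverage used for the default clamp margin;
#'   defaults to `ds$psc$coverage` when present.
#' @return An object of class `pleio_analysis`; see Details.
#' @details The returned list contains `estimates` (one row per SNP,
#'   window, polarization set, and mixture replicate, with `q_b`, `q_f`,
#'   `delta_t`, `s`, `clamped`, `origin_class`, `analysis_window`, `pair`,
#'   `mix_rep`, `polarized_in`), `pairs` (per-pair summaries: mean AFC of
#'   both classes per window with bootstrap CIs, frequency-bin summary,
#'   cost of pleiotropy, realized parental selection, control AFC),
#'   `fst_parental` (pairwise mean Hudson FST at the adaptation endpoint),
#'   `pca` (all parental 110-130 and mixed samples), and `log` (filter
#'   counts).
#' @export
analyze_experiment <- function(ds, thresholds = analysis_thresholds(),
                               design = ds$design,
                               coverage = NULL) {
  if (is.null(coverage)) {
    coverage <- if (!is.null(ds$psc)) ds$psc$coverage else 50
  }
  eps <- thresholds$boundary_eps
  if (is.null(eps)) eps <- 1 / (2 * coverage)
  truth <- ds$truth
  l <- nrow(truth)
  t_adapt <- design$parental_timepoints[2]  # timepoints sorted: 0, T, ...
  g0 <- "g0"
  g110 <- paste0("g", t_adapt)
  late <- paste0("g", design$parental_timepoints[length(design$parental_timepoints)])

  # pooled polymorphism filter on summed counts of the two alleles
  ben_tot <- Reduce(`+`, lapply(c(ds$parents, ds$mixed),
                                function(p) rowSums(p$count, na.rm = TRUE)))
  dep_tot <- Reduce(`+`, lapply(c(ds$parents, ds$mixed),
                                function(p) rowSums(p$depth, na.rm = TRUE)))
  oth_tot <- dep_tot - ben_tot
  keep <- ben_tot >= thresholds$min_count & oth_tot >= thresholds$min_count
  log <- list(n_loci = l, n_polymorphic = sum(keep))

  par_freq <- lapply(ds$parents, function(p) p$freq[keep, , drop = FALSE])
  truth_k <- truth[keep, , drop = FALSE]
  alleles <- data.frame(chrom = truth_k$chrom, pos = truth_k$pos,
                        major = truth_k$beneficial_base,
                        minor = truth_k$ref_base, stringsAsFactors = FALSE)

  # per-parent polarization + conditioning
  polarized <- lapply(seq_along(par_freq), function(r) {
    pol <- polarize_to_rising(par_freq[[r]][, g0], par_freq[[r]][, g110],
                              alleles, source_replicate = paste0("P", r))
    cond <- condition_snps(pol, max_freq = thresholds$max_freq)
    list(polarized = pol, conditioned = cond)
  })
  log$polarized <- vapply(polarized, function(x) nrow(x$polarized), 0L)
  log$conditioned <- vapply(polarized, function(x) nrow(x$conditioned), 0L)

  # helper: beneficial-allele frequency in any sample column
  ofreq <- function(freq_col, snps) {
    i <- match(snps$pos, truth_k$pos)
    oriented_freq(freq_col[i], truth_k$beneficial_base[i],
                  snps$beneficial_allele)
  }

  est_rows <- list()
  pair_results <- list()
  for (p in design$pairs) {
    lbl <- pair_label(p)
    imm <- polarized[[p[1]]]$conditioned
    rec <- polarized[[p[2]]]$conditioned
    origin <- assign_origin(imm, rec)
    oc_imm <- origin$origin_class[match(imm$pos, origin$pos)]
    oc_rec <- origin$origin_class[match(rec$pos, origin$pos)]

    mw <- design$mixed_timepoints
    windows <- lapply(seq_len(length(mw) - 1),
                      function(i) paste0("F", mw[c(i, i + 1)]))
    mix_names <- names(ds$mixed)[vapply(ds$mixed, function(m) {
      m$immigrant == p[1] && m$recipient == p[2]
    }, logical(1))]

    for (nm in mix_names) {
      mx <- ds$mixed[[nm]]
      for (w in windows) {
        gens <- as.integer(sub("F", "", w))
        dt <- diff(gens)
        for (side in c("immigrant", "recipient")) {
          snps <- if (side == "immigrant") imm else rec
          ocl <- if (side == "immigrant") oc_imm else oc_rec
          qb <- ofreq(mx$freq[, w[1]], snps)
          qf <- ofreq(mx$freq[, w[2]], snps)
          ok <- !is.na(qb) & !is.na(qf)
          est <- estimate_s(qb[ok], qf[ok], dt, boundary_eps = eps)
          est_rows[[length(est_rows) + 1]] <- data.frame(
            chrom = snps$chrom[ok], pos = snps$pos[ok], est,
            origin_class = ocl[ok],
            analysis_window = paste(w, collapse = "->"),
            pair = lbl, mix_rep = mx$mix_rep, polarized_in = side,
            stringsAsFactors = FALSE)
        }
      }
    }

    # parental windows for the immigrant parent's conditioned set
    for (side in c("immigrant", "recipient")) {
      r <- if (side == "immigrant") p[1] else p[2]
      snps <- if (side == "immigrant") imm else rec
      ocl <- if (side == "immigrant") oc_imm else oc_rec
      qb <- ofreq(par_freq[[r]][, g0], snps)
      qf <- ofreq(par_freq[[r]][, g110], snps)
      ok <- !is.na(qb) & !is.na(qf)
      est <- estimate_s(qb[ok], qf[ok], t_adapt, boundary_eps = eps)
      est_rows[[length(est_rows) + 1]] <- data.frame(
        chrom = snps$chrom[ok], pos = snps$pos[ok], est,
        origin_class = ocl[ok],
        analysis_window = sprintf("parental 0->%d", t_adapt),
        pair = lbl, mix_rep = NA_integer_, polarized_in = side,
        stringsAsFactors = FALSE)
    }
    pair_results[[lbl]] <- list(pair = p, origin = origin)
  }
  estimates <- do.call(rbind, est_rows)

  # analysis windows over consecutive mixed timepoints (early, late)
  mw <- design$mixed_timepoints
  wlab <- vapply(seq_len(length(mw) - 1),
                 function(i) sprintf("F%d->F%d", mw[i], mw[i + 1]), "")

  # per-pair summaries from the pooled estimate table
  for (lbl in names(pair_results)) {
    e <- estimates[estimates$pair == lbl, ]
    f1f20 <- e[e$analysis_window == wlab[1], ]
    f20f29 <- e[e$analysis_window == wlab[min(2, length(wlab))], ]
    imm1 <- f1f20[f1f20$polarized_in == "immigrant", ]
    rec1 <- f1f20[f1f20$polarized_in == "recipient", ]
    res <- pair_results[[lbl]]
    res$afc_immigrant_f1_f20 <- mean_afc(imm1$q_b, imm1$q_f,
                                         n_boot = thresholds$n_boot)
    res$afc_recipient_f1_f20 <- mean_afc(rec1$q_b, rec1$q_f,
                                         n_boot = thresholds$n_boot)
    imm2 <- f20f29[f20f29$polarized_in == "immigrant", ]
    res$afc_immigrant_f20_f29 <- mean_afc(imm2$q_b, imm2$q_f,
                                          n_boot = thresholds$n_boot)
    res$bins <- bin_by_start_frequency(imm1$q_b, imm1$q_f - imm1$q_b,
                                       bins = thresholds$bins,
                                       n_perm = thresholds$n_perm)
    # focal class = alleles polarized in the immigrant parent (the class
    # the admixture analysis tracks); the exclusive origin partition stays
    # available in the estimates table for stratification
    res$cost <- cost_of_pleiotropy(transform(imm1, origin_class = polarized_in),
                                   focal_origin = "immigrant",
                                   n_boot = thresholds$n_boot)
    par_imm <- e[e$analysis_window == sprintf("parental 0->%d", t_adapt) &
                   e$polarized_in == "immigrant", ]
    res$realized_s <- mean(par_imm$s, na.rm = TRUE)
    res$cost_to_realized_ratio <- res$cost$cost / res$realized_s

    # unmixed parental control over the matching wall-clock window
    p <- res$pair
    imm <- polarized[[p[1]]]$conditioned
    q110 <- ofreq(par_freq[[p[1]]][, g110], imm)
    q130 <- ofreq(par_freq[[p[1]]][, late], imm)
    ok <- !is.na(q110) & !is.na(q130)
    res$control_afc <- control_afc(q110[ok], q130[ok],
                                   n_boot = thresholds$n_boot)
    pair_results[[lbl]] <- res
  }

  # divergence: parental FST at the time of admixture, PCA of all samples
  par110 <- vapply(par_freq, function(f) f[, g110], numeric(sum(keep)))
  colnames(par110) <- paste0("P", seq_along(par_freq))
  fst_parental <- fst_all_pairs(par110)

  pca_cols <- list()
  labels <- list()
  for (r in seq_along(par_freq)) {
    for (tp in colnames(par_freq[[r]])) {
      if (tp == g0) next
      pca_cols[[paste0("P", r, "_", tp)]] <- par_freq[[r]][, tp]
      labels[[length(labels) + 1]] <- data.frame(
        population = paste0("P", r), type = "parental",
        generation = as.integer(sub("g", "", tp)))
    }
  }
  for (nm in names(ds$mixed)) {
    mx <- ds$mixed[[nm]]
    for (tp in colnames(mx$freq)) {
      pca_cols[[paste0(gsub(">", "v", nm), "_", tp)]] <- mx$freq[keep, tp]
      labels[[length(labels) + 1]] <- data.frame(
        population = nm, type = "mixed",
        generation = as.integer(sub("F", "", tp)))
    }
  }
  pca <- pca_frequencies(do.call(cbind, pca_cols),
                         sample_labels = do.call(rbind, labels),
                         n_components = 2)

  structure(list(estimates = estimates, pairs = pair_results,
                 fst_parental = fst_parental, pca = pca, log = log,
                 thresholds = thresholds, boundary_eps = eps,
                 window_labels = wlab),
            class = "pleio_analysis")
}

#' Pooled class means across all pairs and mixture replicates
#'
#' Convenience summary of a [analyze_experiment()] result: the mean F1-F20
#' allele-frequency change of the immigrant- and recipient-polarized
#' classes pooled over pairs and mixture replicates, with bootstrap CIs,
#' plus the pooled frequency--response correlation, cost of pleiotropy, and
#' realized parental selection.
#'
#' @param an a `pleio_analysis`.
#' @param n_boot,n_perm resampling sizes.
#' @return A list of pooled summaries.
#' @export
pooled_summary <- function(an, n_boot = 1000, n_perm = 1000) {
  e <- an$estimates
  wlab <- an$window_labels
  f1f20 <- e[e$analysis_window == wlab[1], ]
  imm <- f1f20[f1f20$polarized_in == "immigrant", ]
  rec <- f1f20[f1f20$polarized_in == "recipient", ]
  imm_late <- e[e$analysis_window == wlab[min(2, length(wlab))] &
                  e$polarized_in == "immigrant", ]
  par_imm <- e[grepl("^parental", e$analysis_window) &
                 e$polarized_in == "immigrant", ]
  d_imm <- imm$q_f - imm$q_b
  d_rec <- rec$q_f - rec$q_b
  asym <- c(d_imm, -d_rec)
  list(
    afc_immigrant = mean_afc(imm$q_b, imm$q_f, n_boot = n_boot),
    afc_recipient = mean_afc(rec$q_b, rec$q_f, n_boot = n_boot),
    afc_immigrant_late = mean_afc(imm_late$q_b, imm_late$q_f,
                                  n_boot = n_boot),
    diff_ci = {
      # bootstrap CI of (mean immigrant AFC - mean recipient AFC)
      bs <- vapply(seq_len(n_boot), function(i) {
        mean(d_imm[sample.int(length(d_imm), replace = TRUE)]) -
          mean(d_rec[sample.int(length(d_rec), replace = TRUE)])
      }, numeric(1))
      unname(stats::quantile(bs, c(0.025, 0.975)))
    },
    bins = bin_by_start_frequency(imm$q_b, d_imm, n_perm = n_perm),
    cost = cost_of_pleiotropy(transform(imm, origin_class = polarized_in),
                              focal_origin = "immigrant", n_boot = n_boot),
    realized_s = mean(par_imm$s, na.rm = TRUE),
    n_immigrant = nrow(imm), n_recipient = nrow(rec)
  )
}
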