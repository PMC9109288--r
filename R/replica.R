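#' Desk-scale replica of the admixture experiment
#'
#' Runs a scaled-down but complete end-to-end replica: two parental
#' replicates with disjoint selected-locus subsets, both ordered 15:85
#' mixtures founded in triplicate and evolved for 29 generations,
#' everything Pool-Seq sampled, and the full inference chain applied. By
#' default (`parental_mode = "designated"`) the post-adaptation parents are
#' constructed with designated disjoint selected sets via
#' [run_designated_experiment()], which pins the parental differentiation
#' that the masking test needs; `parental_mode = "adaptive"` instead runs
#' the full two-phase simulation with [run_experiment()], where selected
#' subsets arise stochastically from a redundant architecture (a larger,
#' noisier scenario whose class contrast depends on the realized
#' divergence). The report carries the four headline checks of the masking
#' mechanism:
#'
#' 1. *Asymmetry*: immigrant-beneficial alleles rise between F1 and F20
#'    while recipient-beneficial alleles fall.
#' 2. *Frequency dependence*: starting frequency and F1-F20 change of
#'    immigrant-beneficial alleles are negatively rank-correlated.
#' 3. *Cost below realized advantage*: the cost of pleiotropy is positive
#'    but smaller than the realized parental selection coefficient.
#' 4. *PCA movement*: mixed F20/F29 samples lie closer to the immigrant
#'    founder than the F1 samples.
#'
#' A check whose direction holds but whose interval is uninformative at
#' this scale is reported as inconclusive rather than passed.
#'
#' @param seed master seed.
#' @param n_loci,census,coverage scale parameters (defaults 60 loci,
#'   census 300, coverage 40).
#' @param cost,cost_dominance pleiotropic cost per locus and its dominance
#'   (defaults 0.05 and 0: weak, fully recessive).
#' @param mix_proportion immigrant fraction (default 0.15).
#' @param n_mix_reps mixture replicates per ordered pair (default 3).
#' @param parental_mode `"designated"` (constructed disjoint selected sets,
#'   the default) or `"adaptive"` (full two-phase simulation).
#' @param thresholds an [analysis_thresholds()] list.
#' @return An object of class `replica_report`: `checks` (data.frame with
#'   one row per headline check), `summary` (pooled statistics), `analysis`
#'   (the full `pleio_analysis`), and `dataset`.
#' @export
run_replica <- function(seed = 1, n_loci = 60, census = 300, coverage = 40,
                        cost = 0.05, cost_dominance = 0,
                        mix_proportion = 0.15, n_mix_reps = 3,
                        parental_mode = c("designated", "adaptive"),
                        thresholds = analysis_thresholds()) {
  parental_mode <- match.arg(parental_mode)
  design <- experiment_design(n_parents = 2,
                              pairs = list(c(1, 2), c(2, 1)),
                              n_mix_reps = n_mix_reps)
  psc <- poolseq_config(coverage = coverage)
  if (parental_mode == "designated") {
    # stabilizing selection strong enough to hold populations at the trait
    # optimum (omega^2 ~ L gives Vs of a few phenotypic variances), so the
    # mixture dynamics are compensatory rather than a sagging trait mean
    cfg <- sim_config(n_loci = n_loci, census_size = census,
                      selection_width = sqrt(n_loci),
                      cost_per_locus = cost,
                      cost_dominance = cost_dominance,
                      mix_proportion = mix_proportion, seed = seed)
    ds <- run_designated_experiment(cfg, psc, design,
                                    n_selected = n_loci %/% 2)
  } else {
    # redundant architecture: rare standing variants, strong stabilizing
    # selection, new optimum reachable by a quarter of the loci
    cfg <- sim_config(n_loci = n_loci, census_size = census,
                      init_freqs = 0.005,
                      optimum_new = 2 * n_loci * 0.005 + 0.3 * n_loci,
                      selection_width = sqrt(2 * n_loci),
                      cost_per_locus = cost,
                      cost_dominance = cost_dominance,
                      mix_proportion = mix_proportion, seed = seed)
    ds <- run_experiment(cfg, psc, design)
  }
  an <- analyze_experiment(ds, thresholds = thresholds)
  sm <- pooled_summary(an, n_boot = thresholds$n_boot,
                       n_perm = thresholds$n_perm)

  pca_move <- pca_movement(an)

  verdict <- function(direction_holds, informative) {
    if (!informative) "inconclusive" else if (direction_holds) "pass" else "fail"
  }
  checks <- rbind(
    data.frame(check = "immigrant_vs_recipient_asymmetry",
               value = sm$afc_immigrant$mean - sm$afc_recipient$mean,
               detail = sprintf("imm %.4f [%.4f, %.4f]; rec %.4f [%.4f, %.4f]",
                                sm$afc_immigrant$mean, sm$afc_immigrant$ci[1],
                                sm$afc_immigrant$ci[2], sm$afc_recipient$mean,
                                sm$afc_recipient$ci[1], sm$afc_recipient$ci[2]),
               result = verdict(sm$afc_immigrant$mean > 0 &&
                                  sm$afc_immigrant$mean > sm$afc_recipient$mean &&
                                  sm$diff_ci[1] > 0,
                                sm$n_immigrant >= 10 && sm$n_recipient >= 10)),
    data.frame(check = "negative_frequency_response_correlation",
               value = sm$bins$correlation,
               detail = sprintf("rho %.3f, permutation p %.4f",
                                sm$bins$correlation, sm$bins$p_perm),
               result = verdict(!is.na(sm$bins$correlation) &&
                                  sm$bins$correlation < 0 &&
                                  sm$bins$p_perm < 0.05,
                                sm$bins$n >= 10)),
    data.frame(check = "cost_below_realized_advantage",
               value = sm$cost$cost / sm$realized_s,
               detail = sprintf("cost %.4f [%.4f, %.4f]; realized s %.4f",
                                sm$cost$cost, sm$cost$ci[1], sm$cost$ci[2],
                                sm$realized_s),
               result = verdict(sm$cost$ci[1] > 0 &&
                                  sm$cost$cost < sm$realized_s,
                                sm$cost$n >= 10 && sm$realized_s > 0)),
    data.frame(check = "pca_movement_toward_immigrant",
               value = pca_move$ratio,
               detail = sprintf("mean dist to immigrant founder: F1 %.3f, late %.3f",
                                pca_move$d_f1, pca_move$d_late),
               result = verdict(pca_move$d_late < pca_move$d_f1,
                                is.finite(pca_move$ratio)))
  )
  structure(list(checks = checks, summary = sm, analysis = an, dataset = ds,
                 seed = seed),
            class = "replica_report")
}

# Mean PC1/PC2 distance of mixed samples to their immigrant founder's
# coordinates at the adaptation endpoint, F1 vs F20/F29.
pca_movement <- function(an) {
  co <- an$pca$coordinates
  pcs <- as.matrix(co[, c("PC1", "PC2")])
  d_f1 <- c()
  d_late <- c()
  mixed <- which(co$type == "mixed")
  for (i in mixed) {
    popname <- co$population[i]
    imm_id <- an$pairs[[sub("\\.r[0-9]+$", "", popname)]]$pair[1]
    anchor_row <- which(co$type == "parental" &
                          co$population == paste0("P", imm_id))
    anchor_row <- anchor_row[which.min(co$generation[anchor_row])]
    d <- sqrt(sum((pcs[i, ] - pcs[anchor_row, ])^2))
    if (co$generation[i] == 1) d_f1 <- c(d_f1, d) else d_late <- c(d_late, d)
  }
  list(d_f1 = mean(d_f1), d_late = mean(d_late),
       ratio = mean(d_late) / mean(d_f1))
}

#' @export
print.replica_report <- function(x, ...) {
  cat(sprintf("Admixture replica (seed %d)\n", x$seed))
  cat(sprintf("  SNPs: %d polymorphic of %d loci; immigrant class n = %d, recipient n = %d\n",
              x$analysis$log$n_polymorphic, x$analysis$log$n_loci,
              x$summary$n_immigrant, x$summary$n_recipient))
  for (i in seq_len(nrow(x$checks))) {
    cat(sprintf("  [%-12s] %s = %.4f (%s)\n", x$checks$result[i],
                x$checks$check[i], x$checks$value[i], x$checks$detail[i]))
  }
  invisible(x)
}

#' Construct an adapted parental population with a designated selected set
#'
#' Builds a population directly in the post-adaptation state: the loci in
#' `selected` carry the beneficial allele at frequency `q_selected`, all
#' other loci sit at `q_background`. Used for controlled differentiation
#' experiments where the overlap between two parents' selected sets must be
#' fixed by design rather than arise stochastically.
#'
#' @param cfg a [sim_config()].
#' @param selected integer vector of selected locus indices.
#' @param q_selected,q_background allele frequencies of selected and
#'   background loci.
#' @return A [population_state()].
#' @export
make_adapted_population <- function(cfg, selected, q_selected = 0.8,
                                    q_background = 0.05) {
  q <- rep(q_background, cfg$n_loci)
  q[selected] <- q_selected
  cfg2 <- cfg
  cfg2$init_freqs <- q
  founder_population(cfg2)
}

#' Differentiation-ordering experiment over constructed population pairs
#'
#' For each requested overlap fraction, constructs an (immigrant,
#' recipient) pair of populations whose designated selected sets (of equal
#' size) share that fraction of loci, with the trait optimum set to the
#' common population mean so the mixture dynamics are driven by the
#' pleiotropic cost alone. Measures (a) the mean pairwise Hudson FST
#' between the two parents from Pool-Seq samples at the time of mixture and
#' (b) the mean F1-F20 frequency change of the immigrant parent's selected
#' alleles across mixture replicates. Pairs sharing more selected loci are
#' expected to show both lower FST and a weaker immigrant advantage.
#'
#' @param seed master seed.
#' @param overlaps numeric vector of selected-set overlap fractions.
#' @param n_loci,census,coverage,cost,n_mix_reps scale parameters.
#' @param n_selected selected-set size per parent (default `n_loci / 3`).
#' @param q_selected frequency of selected alleles in their parent.
#' @return A data.frame with one row per overlap: `overlap`, `fst`,
#'   `immigrant_afc`.
#' @export
divergence_ordering <- function(seed = 1, overlaps = c(0, 0.5),
                                n_loci = 60, census = 300, coverage = 40,
                                cost = 0.05, n_mix_reps = 3,
                                n_selected = round(n_loci / 3),
                                q_selected = 0.8) {
  out <- list()
  for (ov in overlaps) {
    cfg <- sim_config(n_loci = n_loci, census_size = census,
                      cost_per_locus = cost, cost_dominance = 0,
                      seed = seed)
    n_shared <- round(ov * n_selected)
    sel_imm <- seq_len(n_selected)
    sel_rec <- c(seq_len(n_shared),
                 n_selected + seq_len(n_selected - n_shared))
    # optimum at the common mean so the mixture stays trait-neutral
    q_bg <- cfg$init_freqs[1]
    zbar <- 2 * sum(cfg$effect_sizes[sel_imm]) * q_selected +
      2 * sum(cfg$effect_sizes[-sel_imm]) * q_bg
    cfg$optimum_new <- zbar
    psc <- poolseq_config(coverage = coverage)

    set.seed(derive_seed(seed, "divergence", ov))
    pop_imm <- make_adapted_population(cfg, sel_imm, q_selected, q_bg)
    pop_rec <- make_adapted_population(cfg, sel_rec, q_selected, q_bg)
    f_imm <- pool_seq_sample(pop_imm, psc)
    f_rec <- pool_seq_sample(pop_rec, psc)
    fmat <- cbind(imm = f_imm[, 1] / rowSums(f_imm),
                  rec = f_rec[, 1] / rowSums(f_rec))
    fst <- fst_pairwise(fmat, c("imm", "rec"))$mean

    afc <- c()
    for (k in seq_len(n_mix_reps)) {
      set.seed(derive_seed(seed, "divmix", ov, k))
      pop <- admix(pop_imm, pop_rec, m = cfg$mix_proportion,
                   n = cfg$census_size)
      freqs <- list()
      for (t in 1:20) {
        pop <- advance_generation(pop, cfg, cfg$optimum_new)
        if (t %in% c(1, 20)) {
          ps <- pool_seq_sample(pop, psc)
          freqs[[as.character(t)]] <- ps[, 1] / rowSums(ps)
        }
      }
      afc <- c(afc, mean(freqs[["20"]][sel_imm] - freqs[["1"]][sel_imm],
                         na.rm = TRUE))
    }
    out[[length(out) + 1]] <- data.frame(overlap = ov, fst = fst,
                                         immigrant_afc = mean(afc))
  }
  do.call(rbind, out)
}
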