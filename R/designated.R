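#' Simulate the admixture experiment from designated parental states
#'
#' Controlled variant of [run_experiment()]: instead of letting each
#' parental replicate choose its selected subset stochastically during the
#' adaptation phase, the post-adaptation parental populations are
#' constructed directly, each with a *designated* selected-locus set at
#' frequency `q_selected` and all other loci at the background frequency
#' `q_background` (via [make_adapted_population()]). This fixes the overlap
#' between parental selected sets by design -- disjoint sets by default --
#' which is the regime where the masking prediction is sharpest and the
#' ground truth is exact. Everything downstream is identical to the full
#' two-phase simulation: the generation-0 sample is drawn from a founder
#' population at the background frequency, parents continue under
#' stabilizing selection (with the optimum at the constructed population
#' mean, so parents start at their optimum) through the late control
#' timepoints, mixtures are founded at the immigrant fraction `m` in
#' replicate and evolved through the mixture phase, and all samples pass
#' through the Pool-Seq noise model.
#'
#' @param cfg a [sim_config()]; `optimum_new` is overridden to the
#'   constructed parental trait mean.
#' @param psc a [poolseq_config()].
#' @param design an [experiment_design()].
#' @param selected_sets list (length `n_parents`) of locus index vectors;
#'   `NULL` designates consecutive disjoint blocks of `n_selected` loci.
#' @param n_selected designated selected-set size per parent when
#'   `selected_sets` is `NULL` (default `n_loci %/% (2 * n_parents)` kept
#'   modest so background loci remain).
#' @param q_selected,q_background constructed frequencies (defaults 0.8 and
#'   0.05).
#' @param seed master seed (default `cfg$seed`).
#' @return An `experiment_dataset`, exactly as from [run_experiment()].
#' @export
run_designated_experiment <- function(cfg, psc = poolseq_config(),
                                      design = experiment_design(),
                                      selected_sets = NULL,
                                      n_selected = cfg$n_loci %/%
                                        max(4, 2 * design$n_parents),
                                      q_selected = 0.8,
                                      q_background = 0.05,
                                      seed = cfg$seed) {
  if (is.null(seed)) stop("a master seed is required (cfg$seed or seed =)")
  if (is.null(selected_sets)) {
    if (design$n_parents * n_selected > cfg$n_loci) {
      stop("designated sets exceed the number of loci")
    }
    selected_sets <- lapply(seq_len(design$n_parents), function(r) {
      (r - 1) * n_selected + seq_len(n_selected)
    })
  }
  stopifnot(length(selected_sets) == design$n_parents)
  l <- cfg$n_loci
  t_adapt <- design$parental_timepoints[2]
  t_max <- max(design$parental_timepoints)

  # all parents carry the same number of selected loci, so they share the
  # trait mean; putting the optimum there makes the mixture trait-neutral
  # and leaves the pleiotropic cost as the only directional force
  k <- length(selected_sets[[1]])
  if (any(lengths(selected_sets) != k)) {
    stop("designated sets must have equal size across parents")
  }
  a <- cfg$effect_sizes
  cfg$optimum_new <- 2 * (sum(a[selected_sets[[1]]]) * q_selected +
                            sum(a[-selected_sets[[1]]]) * q_background)
  cfg$init_freqs <- rep(q_background, l)

  tp_names <- paste0("g", design$parental_timepoints)
  parents <- vector("list", design$n_parents)
  states110 <- vector("list", design$n_parents)
  dp_true <- matrix(NA_real_, l, design$n_parents)
  for (r in seq_len(design$n_parents)) {
    set.seed(derive_seed(seed, "designated-parent", r))
    founder <- founder_population(cfg)
    pop <- make_adapted_population(cfg, selected_sets[[r]], q_selected,
                                   q_background)
    states110[[r]] <- pop
    count <- depth <- true_freq <- matrix(
      NA_real_, l, length(design$parental_timepoints),
      dimnames = list(NULL, tp_names))
    record <- function(p, gen) {
      j <- match(gen, design$parental_timepoints)
      ps <- pool_seq_sample(p, psc)
      count[, j] <<- ps[, "beneficial"]
      depth[, j] <<- rowSums(ps)
      true_freq[, j] <<- allele_freqs(p)
    }
    record(founder, 0)
    record(pop, t_adapt)
    for (t in seq(t_adapt + 1, length.out = t_max - t_adapt)) {
      pop <- advance_generation(pop, cfg, cfg$optimum_new)
      if (t %in% design$parental_timepoints) record(pop, t)
    }
    dp_true[, r] <- true_freq[, match(t_adapt, design$parental_timepoints)] -
      true_freq[, 1]
    parents[[r]] <- list(count = count, depth = depth,
                         freq = ifelse(depth > 0, count / depth, NA_real_),
                         true_freq = true_freq)
  }

  mtp_names <- paste0("F", design$mixed_timepoints)
  mixed <- list()
  for (p in design$pairs) {
    for (kk in seq_len(design$n_mix_reps)) {
      set.seed(derive_seed(seed, "designated-mix", p[1], p[2], kk))
      pop <- admix(states110[[p[1]]], states110[[p[2]]],
                   m = cfg$mix_proportion, n = cfg$census_size)
      count <- depth <- true_freq <- matrix(
        NA_real_, l, length(design$mixed_timepoints),
        dimnames = list(NULL, mtp_names))
      for (t in seq_len(max(design$mixed_timepoints))) {
        pop <- advance_generation(pop, cfg, cfg$optimum_new)
        j <- match(t, design$mixed_timepoints)
        if (!is.na(j)) {
          ps <- pool_seq_sample(pop, psc)
          count[, j] <- ps[, "beneficial"]
          depth[, j] <- rowSums(ps)
          true_freq[, j] <- allele_freqs(pop)
        }
      }
      mixed[[sprintf("%s.r%d", pair_label(p), kk)]] <-
        list(immigrant = p[1], recipient = p[2], mix_rep = kk,
             count = count, depth = depth,
             freq = ifelse(depth > 0, count / depth, NA_real_),
             true_freq = true_freq)
    }
  }

  set.seed(derive_seed(seed, "bases"))
  bases <- c("A", "T", "C", "G")
  ref <- sample(bases, l, replace = TRUE)
  beneficial <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  truth <- data.frame(
    locus = seq_len(l), chrom = "sim1", pos = 1000L * seq_len(l),
    ref_base = ref, beneficial_base = unname(beneficial),
    a = cfg$effect_sizes, c = cfg$cost_per_locus,
    stringsAsFactors = FALSE
  )
  for (r in seq_len(design$n_parents)) {
    truth[[sprintf("dp_P%d", r)]] <- dp_true[, r]
    truth[[sprintf("selected_P%d", r)]] <-
      seq_len(l) %in% selected_sets[[r]]
  }

  structure(list(parents = parents, mixed = mixed, truth = truth,
                 cfg = cfg, psc = psc, design = design, seed = seed,
                 selected_sets = selected_sets),
            class = "experiment_dataset")
}
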