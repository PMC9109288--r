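# Shared parameterization of the desk-scale experiment driven by the
# analysis scripts. The design mirrors the admixture study: 4 parental
# replicates sampled at generations 0/110/120/130, both orderings of two
# population pairs mixed 15:85 in triplicate and sampled at F1/F20/F29.
# The trait architecture is redundant (100 candidate loci, rare standing
# variants, a new optimum reachable by about a quarter of them), so each
# parental replicate adapts through its own stochastic subset of loci.

library(pleiocost)

MASTER_SEED <- 20260927
N_LOCI <- 100

experiment_cfg <- function() {
  sim_config(
    n_loci = N_LOCI,
    census_size = 300,
    init_freqs = 0.005,
    optimum_new = 2 * N_LOCI * 0.005 + 0.3 * N_LOCI,
    selection_width = sqrt(2 * N_LOCI),
    cost_per_locus = 0.05,
    cost_dominance = 0,
    mix_proportion = 0.15,
    seed = MASTER_SEED
  )
}

experiment_psc <- function() poolseq_config(coverage = 50)

experiment_plan <- function() {
  experiment_design(
    n_parents = 4,
    pairs = list(c(1, 2), c(2, 1), c(3, 4), c(4, 3)),
    n_mix_reps = 3
  )
}

RESULTS_DIR <- file.path("results")
EXPERIMENT_DIR <- file.path(RESULTS_DIR, "experiment")
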