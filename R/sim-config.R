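#' Configuration of the two-phase admixture simulation
#'
#' Parameterizes an individual-based diploid Wright--Fisher simulation of
#' (phase 1) polygenic adaptation to a shifted trait optimum under Gaussian
#' stabilizing selection with per-locus pleiotropic fitness costs, and
#' (phase 2) imbalanced admixture between independently adapted replicate
#' populations.
#'
#' Per-locus arguments (`effect_sizes`, `init_freqs`, `trait_dominance`,
#' `cost_per_locus`) are recycled to length `n_loci`.
#'
#' Defaults encode the experimental design this simulator emulates: a census
#' of 1250 diploids kept constant across non-overlapping generations, 110
#' generations of adaptation, mixture at a 15:85 immigrant:recipient ratio,
#' and 29 further generations. The default trait architecture is redundant:
#' beneficial alleles start at frequency 0.05, the population starts at the
#' old optimum, and the new optimum requires only about half of the total
#' additive capacity, so replicate populations can (and do) reach it with
#' different subsets of loci. The default cost is weakly deleterious
#' (c = 0.05 per locus) and fully recessive (`cost_dominance = 0`), while
#' trait effects are additive (`trait_dominance = 0.5`).
#'
#' @param n_loci number of biallelic trait loci.
#' @param census_size constant number of diploid individuals.
#' @param effect_sizes per-locus additive trait effect of the beneficial
#'   allele, in trait units (homozygote contributes `2 * a`).
#' @param init_freqs per-locus starting frequency of the beneficial allele
#'   in the founder population.
#' @param optimum_old,optimum_new trait optima (trait units). Defaults put
#'   the founder mean at the old optimum and set the new optimum to half of
#'   the maximal attainable trait value.
#' @param selection_width width `omega` of the Gaussian stabilizing-selection
#'   fitness function, in trait units; `Inf` disables trait selection.
#' @param trait_dominance per-locus dominance of the beneficial allele on
#'   the trait, in \[0, 1\]; 0.5 is additive.
#' @param cost_per_locus per-locus pleiotropic fitness cost c in \[0, 1).
#' @param cost_dominance dominance h_c of the pleiotropic cost in \[0, 1\];
#'   0 means fully recessive (cost expressed only in homozygotes).
#' @param recomb_model `"free"` for unlinked loci, or a numeric vector of
#'   length `n_loci - 1` of recombination fractions between adjacent loci.
#' @param adapt_generations length of the adaptation phase.
#' @param mix_generations generations of evolution after admixture.
#' @param mix_proportion immigrant fraction m of the mixture, in (0, 1).
#' @param seed optional integer master seed used by [run_experiment()].
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [poolseq_config()], [run_experiment()], [individual_fitness()]
#' @export
#' @examples
#' cfg <- sim_config(n_loci = 20, census_size = 100)
#' cfg$optimum_new
sim_config <- function(n_loci,
                       census_size = 1250,
                       effect_sizes = 1,
                       init_freqs = 0.05,
                       optimum_old = NULL,
                       optimum_new = NULL,
                       selection_width = NULL,
                       trait_dominance = 0.5,
                       cost_per_locus = 0.05,
                       cost_dominance = 0,
                       recomb_model = "free",
                       adapt_generations = 110,
                       mix_generations = 29,
                       mix_proportion = 0.15,
                       seed = NULL) {
  stopifnot(is.numeric(n_loci), length(n_loci) == 1, n_loci >= 1)
  n_loci <- as.integer(n_loci)
  effect_sizes <- rep_len(as.numeric(effect_sizes), n_loci)
  init_freqs <- rep_len(as.numeric(init_freqs), n_loci)
  trait_dominance <- rep_len(as.numeric(trait_dominance), n_loci)
  cost_per_locus <- rep_len(as.numeric(cost_per_locus), n_loci)

  if (is.null(optimum_old)) {
    optimum_old <- 2 * sum(effect_sizes * init_freqs)
  }
  if (is.null(optimum_new)) {
    optimum_new <- 0.5 * sum(abs(effect_sizes))
  }
  if (is.null(selection_width)) {
    # scales selection so the initial per-locus gradient is of order 0.1
    tot <- sum(abs(effect_sizes))
    selection_width <- if (tot > 0) sqrt(5 * tot) else Inf
  }

  cfg <- structure(list(
    n_loci = n_loci,
    census_size = as.integer(census_size),
    effect_sizes = effect_sizes,
    init_freqs = init_freqs,
    optimum_old = optimum_old,
    optimum_new = optimum_new,
    selection_width = selection_width,
    trait_dominance = trait_dominance,
    cost_per_locus = cost_per_locus,
    cost_dominance = cost_dominance,
    recomb_model = recomb_model,
    adapt_generations = as.integer(adapt_generations),
    mix_generations = as.integer(mix_generations),
    mix_proportion = mix_proportion,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (census_size < 2) stop("census_size must be >= 2")
    if (!all(is.finite(effect_sizes))) stop("effect sizes must be finite")
    if (any(init_freqs < 0 | init_freqs > 1)) {
      stop("init_freqs must lie in [0, 1]")
    }
    if (any(trait_dominance < 0 | trait_dominance > 1)) {
      stop("trait_dominance must lie in [0, 1]")
    }
    if (any(cost_per_locus < 0 | cost_per_locus >= 1)) {
      stop("cost_per_locus must lie in [0, 1) so fitness stays positive")
    }
    if (cost_dominance < 0 || cost_dominance > 1) {
      stop("cost_dominance must lie in [0, 1]")
    }
    if (mix_proportion <= 0 || mix_proportion >= 1) {
      stop("mix_proportion must lie strictly in (0, 1)")
    }
    if (!(is.infinite(selection_width) || selection_width > 0)) {
      stop("selection_width must be positive (Inf disables trait selection)")
    }
    if (is.character(recomb_model)) {
      if (!identical(recomb_model, "free")) {
        stop("recomb_model must be \"free\" or a numeric vector of fractions")
      }
    } else {
      if (length(recomb_model) != n_loci - 1 ||
          any(recomb_model < 0 | recomb_model > 0.5)) {
        stop("linked recomb_model needs n_loci - 1 fractions in [0, 0.5]")
      }
    }
    if (adapt_generations < 0 || mix_generations < 0) {
      stop("generation counts must be non-negative")
    }
  })
  invisible(cfg)
}

#' Pool-Seq sampling configuration
#'
#' Two-stage pooled-sequencing noise model: a pool of individuals is drawn
#' without replacement from the population, then read counts are drawn
#' binomially from the pool allele frequency at the configured depth.
#'
#' @param coverage mean sequencing depth per site.
#' @param coverage_model `"fixed"` (every site at exactly `coverage`) or
#'   `"poisson"` (per-site depth Poisson-distributed around `coverage`).
#' @param pool_size number of individuals pooled; `NULL` pools the whole
#'   population (the default, matching whole-population DNA pooling).
#'
#' @return An object of class `poolseq_config`.
#' @export
poolseq_config <- function(coverage = 50,
                           coverage_model = c("fixed", "poisson"),
                           pool_size = NULL) {
  coverage_model <- match.arg(coverage_model)
  if (coverage < 1) stop("coverage must be >= 1")
  structure(list(
    coverage = coverage,
    coverage_model = coverage_model,
    pool_size = if (is.null(pool_size)) NULL else as.integer(pool_size)
  ), class = "poolseq_config")
}

#' Derive a reproducible stream seed from a master seed
#'
#' Folds a master seed and a set of string/integer tags into a positive
#' 31-bit integer, so each replicate, mixture, or sampling step gets its own
#' deterministic RNG stream and adding a replicate never perturbs others.
#'
#' @param master integer master seed.
#' @param ... tags (coerced to character) identifying the stream.
#' @return A positive integer seed.
#' @export
derive_seed <- function(master, ...) {
  tag <- paste(vapply(list(...), as.character, ""), collapse = "/")
  h <- as.double(master) %% 2147483647
  for (code in utf8ToInt(tag)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(max(h, 1))
}
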