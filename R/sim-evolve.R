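#' Population state containers and the Wright--Fisher engine
#'
#' A population is a list of two `N x L` 0/1 haplotype matrices (`h1`, `h2`;
#' 1 = beneficial allele), a generation counter, and optional per-allele
#' lineage matrices (`l1`, `l2`; 1 = immigrant origin) that track ancestry
#' through recombination in mixed populations.
#'
#' @param h1,h2 integer/numeric `N x L` matrices with entries in \{0, 1\}.
#' @param generation non-negative integer generation counter.
#' @param l1,l2 optional lineage matrices of the same dimension.
#' @return An object of class `population_state`.
#' @export
population_state <- function(h1, h2, generation = 0L, l1 = NULL, l2 = NULL) {
  if (!identical(dim(h1), dim(h2))) stop("haplotype matrices must match")
  if (any(h1 != 0 & h1 != 1) || any(h2 != 0 & h2 != 1)) {
    stop("haplotype entries must be 0 or 1")
  }
  structure(list(h1 = h1, h2 = h2, generation = as.integer(generation),
                 l1 = l1, l2 = l2),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("population_state: %d diploids x %d loci, generation %d%s\n",
              nrow(x$h1), ncol(x$h1), x$generation,
              if (is.null(x$l1)) "" else " (lineage-tracked)"))
  invisible(x)
}

#' Draw a founder population at linkage equilibrium
#'
#' Haplotypes are drawn per locus as independent Bernoulli(`init_freqs`)
#' variables (linkage equilibrium), emulating a population founded from many
#' independent isofemale lines. With `exact = TRUE` each locus instead gets
#' exactly `round(2N q)` beneficial alleles placed on random haplotypes,
#' which pins the generation-0 frequency for drift calibrations.
#'
#' @param cfg a [sim_config()].
#' @param exact logical; pin initial allele counts to their expectation.
#' @return A [population_state()] at generation 0.
#' @export
founder_population <- function(cfg, exact = FALSE) {
  n <- cfg$census_size
  l <- cfg$n_loci
  if (exact) {
    draw_col <- function(q) {
      k <- round(2 * n * q)
      al <- sample(c(rep(1L, k), rep(0L, 2 * n - k)))
      al
    }
    alleles <- vapply(cfg$init_freqs, draw_col, integer(2 * n))
    h1 <- alleles[seq_len(n), , drop = FALSE]
    h2 <- alleles[n + seq_len(n), , drop = FALSE]
  } else {
    h1 <- matrix(rbinom(n * l, 1L, rep(cfg$init_freqs, each = n)), n, l)
    h2 <- matrix(rbinom(n * l, 1L, rep(cfg$init_freqs, each = n)), n, l)
  }
  population_state(h1, h2, 0L)
}

#' Beneficial-allele frequencies of a population
#'
#' @param pop a [population_state()].
#' @return Numeric vector of length `n_loci` in \[0, 1\].
#' @export
allele_freqs <- function(pop) {
  (colSums(pop$h1) + colSums(pop$h2)) / (2 * nrow(pop$h1))
}

# Vectorized fitness of every individual: Gaussian stabilizing selection on
# the trait times multiplicative per-locus pleiotropic cost terms.
population_fitness <- function(pop, cfg, optimum) {
  g <- pop$h1 + pop$h2
  het <- g == 1L
  hom <- g == 2L
  z <- as.vector(het %*% (2 * cfg$trait_dominance * cfg$effect_sizes) +
                   hom %*% (2 * cfg$effect_sizes))
  if (!all(is.finite(z))) stop("non-finite trait value")
  w_trait <- if (is.infinite(cfg$selection_width)) {
    rep(1, length(z))
  } else {
    exp(-(z - optimum)^2 / (2 * cfg$selection_width^2))
  }
  # cost term: eta = 0 / h_c / 1 for 0 / 1 / 2 copies of the beneficial allele
  log_cost <- as.vector(
    het %*% log1p(-cfg$cost_per_locus * cfg$cost_dominance) +
      hom %*% log1p(-cfg$cost_per_locus)
  )
  w_trait * exp(log_cost)
}

#' Fitness of a single diploid individual
#'
#' Computes `w = exp(-(z - optimum)^2 / (2 omega^2)) * prod_i(1 - c_i eta_i)`
#' where the trait value is `z = sum_i a_i * g(d_i, genotype_i)` with
#' genotype contributions `{0, 2 d_i, 2} * a_i` (additive at d = 0.5), and
#' the cost exposure `eta_i` is 0, `h_c`, or 1 for 0, 1, or 2 copies of the
#' beneficial allele. A fully recessive cost (`h_c = 0`) is therefore
#' completely masked in heterozygotes -- the mechanism behind the
#' post-admixture advantage of rare immigrant alleles.
#'
#' @param h1,h2 binary haplotype vectors of length `n_loci`.
#' @param cfg a [sim_config()].
#' @param optimum trait optimum at which fitness is evaluated.
#' @return A positive scalar fitness.
#' @export
#' @examples
#' cfg <- sim_config(n_loci = 1, census_size = 10, effect_sizes = 1,
#'                   cost_per_locus = 0.2, cost_dominance = 0)
#' individual_fitness(c(1), c(1), cfg, optimum = 2)  # 1 - c = 0.8
individual_fitness <- function(h1, h2, cfg, optimum) {
  stopifnot(length(h1) == cfg$n_loci, length(h2) == cfg$n_loci)
  pop <- population_state(matrix(h1, 1), matrix(h2, 1))
  population_fitness(pop, cfg, optimum)[1]
}

# Recombination mask for n gametes: 1 = take allele from h1. Free
# recombination draws each locus independently; the linked model runs a
# crossover Markov chain along the locus order.
recomb_mask <- function(n, l, recomb_model) {
  if (identical(recomb_model, "free")) {
    return(matrix(rbinom(n * l, 1L, 0.5), n, l))
  }
  s0 <- rbinom(n, 1L, 0.5)
  if (l == 1) return(matrix(s0, n, 1))
  sw <- matrix(rbinom(n * (l - 1), 1L, rep(recomb_model, each = n)), n, l - 1)
  cs <- sw
  for (j in seq_len(l - 1)[-1]) cs[, j] <- cs[, j] + cs[, j - 1]
  (cbind(0L, cs) + s0) %% 2L
}

gametes_from <- function(pop, parents, cfg) {
  n <- length(parents)
  l <- cfg$n_loci
  m <- recomb_mask(n, l, cfg$recomb_model)
  h <- m * pop$h1[parents, , drop = FALSE] +
    (1 - m) * pop$h2[parents, , drop = FALSE]
  lin <- NULL
  if (!is.null(pop$l1)) {
    lin <- m * pop$l1[parents, , drop = FALSE] +
      (1 - m) * pop$l2[parents, , drop = FALSE]
  }
  list(h = h, l = lin)
}

#' Advance a population by one Wright--Fisher generation
#'
#' Produces `N` offspring by fitness-weighted sampling of parent pairs
#' (distinct mother and father); each parent transmits one recombinant
#' haplotype. Lineage labels, when present, are inherited per transmitted
#' allele. The census size is constant.
#'
#' @param pop a [population_state()].
#' @param cfg a [sim_config()].
#' @param optimum trait optimum under which fitness is evaluated.
#' @return The next-generation [population_state()].
#' @export
advance_generation <- function(pop, cfg, optimum) {
  n <- nrow(pop$h1)
  w <- population_fitness(pop, cfg, optimum)
  if (all(w == 0)) stop("population extinct under selection")
  mothers <- sample.int(n, n, replace = TRUE, prob = w)
  fathers <- sample.int(n, n, replace = TRUE, prob = w)
  if (n > 1) {
    clash <- which(fathers == mothers)
    while (length(clash) > 0) {
      fathers[clash] <- sample.int(n, length(clash), replace = TRUE, prob = w)
      clash <- clash[fathers[clash] == mothers[clash]]
    }
  }
  gm <- gametes_from(pop, mothers, cfg)
  gf <- gametes_from(pop, fathers, cfg)
  population_state(gm$h, gf$h, pop$generation + 1L, gm$l, gf$l)
}

#' Run the adaptation phase and record the frequency trajectory
#'
#' Evolves the population for `generations` Wright--Fisher steps toward the
#' given optimum, recording per-locus beneficial-allele frequencies each
#' generation.
#'
#' @param pop starting [population_state()].
#' @param cfg a [sim_config()].
#' @param generations number of generations (default `cfg$adapt_generations`).
#' @param optimum trait optimum (default `cfg$optimum_new`).
#' @return A list with `trajectory` (a `(generations + 1) x n_loci` matrix,
#'   first row the starting frequencies) and `population` (the final state).
#' @export
adapt <- function(pop, cfg, generations = cfg$adapt_generations,
                  optimum = cfg$optimum_new) {
  traj <- matrix(NA_real_, generations + 1, cfg$n_loci)
  traj[1, ] <- allele_freqs(pop)
  for (t in seq_len(generations)) {
    pop <- advance_generation(pop, cfg, optimum)
    traj[t + 1, ] <- allele_freqs(pop)
  }
  list(trajectory = traj, population = pop)
}

#' Mix two populations at an imbalanced ratio
#'
#' Builds a new population of `n` individuals in which the number of
#' immigrants is drawn binomially around `m * n`, mirroring the stochastic
#' sampling of individuals during the setup of a mixed population.
#' Individuals are drawn without replacement from each source when possible.
#' Lineage labels are set (1 = immigrant allele, 0 = recipient allele).
#'
#' @param pop_immigrant,pop_recipient source [population_state()]s sharing
#'   locus indexing.
#' @param m immigrant proportion, in (0, 1); the design value is 0.15.
#' @param n census of the mixed population (default: recipient census).
#' @return A lineage-tracked [population_state()] at generation 0.
#' @export
admix <- function(pop_immigrant, pop_recipient, m = 0.15, n = NULL) {
  if (m <= 0 || m >= 1) stop("mixture proportion m must lie in (0, 1)")
  if (ncol(pop_immigrant$h1) != ncol(pop_recipient$h1)) {
    stop("populations must share locus indexing")
  }
  if (is.null(n)) n <- nrow(pop_recipient$h1)
  n_imm <- rbinom(1, n, m)
  n_rec <- n - n_imm
  pick <- function(pop, k) {
    avail <- nrow(pop$h1)
    if (k == 0) return(integer(0))
    sample.int(avail, k, replace = k > avail)
  }
  ii <- pick(pop_immigrant, n_imm)
  ir <- pick(pop_recipient, n_rec)
  h1 <- rbind(pop_immigrant$h1[ii, , drop = FALSE],
              pop_recipient$h1[ir, , drop = FALSE])
  h2 <- rbind(pop_immigrant$h2[ii, , drop = FALSE],
              pop_recipient$h2[ir, , drop = FALSE])
  lin <- rbind(matrix(1L, n_imm, ncol(h1)), matrix(0L, n_rec, ncol(h1)))
  population_state(h1, h2, 0L, l1 = lin, l2 = lin)
}

#' Pool-Seq sampling of a population
#'
#' Two-stage sampling: (1) the pool allele frequency is computed from
#' `pool_size` individuals drawn without replacement; (2) per-site read
#' counts are binomial at the sampled frequency, with depth either fixed at
#' `coverage` or Poisson-distributed.
#'
#' @param pop a [population_state()].
#' @param psc a [poolseq_config()].
#' @return An integer matrix with one row per locus and columns `beneficial`
#'   and `other`; rows sum to the per-site depth.
#' @export
pool_seq_sample <- function(pop, psc) {
  n <- nrow(pop$h1)
  pool <- if (is.null(psc$pool_size)) n else psc$pool_size
  if (pool > n) stop("pool_size exceeds census size")
  idx <- if (pool == n) seq_len(n) else sample.int(n, pool)
  p <- (colSums(pop$h1[idx, , drop = FALSE]) +
          colSums(pop$h2[idx, , drop = FALSE])) / (2 * pool)
  l <- length(p)
  depth <- switch(psc$coverage_model,
                  fixed = rep(as.integer(round(psc$coverage)), l),
                  poisson = rpois(l, psc$coverage))
  cnt <- rbinom(l, depth, p)
  cbind(beneficial = cnt, other = depth - cnt)
}

#' Neutral Wright--Fisher trajectories for drift calibration
#'
#' Runs `n_runs` independent single-locus, selectively neutral populations
#' (no trait effect, no cost) through the individual-based engine, starting
#' from an exact allele count of `round(2 N p0)`. Used to check the engine
#' against the closed-form drift moments: constant mean and variance
#' `p0 (1 - p0) (1 - (1 - 1/(2N))^t)`.
#'
#' @param n_runs number of replicate populations.
#' @param census diploid census size.
#' @param p0 starting allele frequency.
#' @param generations number of generations.
#' @return Matrix of allele frequencies, `n_runs` rows x
#'   `generations + 1` columns.
#' @export
wf_drift_trajectories <- function(n_runs, census, p0, generations) {
  cfg <- sim_config(n_loci = 1, census_size = census, effect_sizes = 0,
                    init_freqs = p0, cost_per_locus = 0,
                    selection_width = Inf)
  out <- matrix(NA_real_, n_runs, generations + 1)
  for (r in seq_len(n_runs)) {
    pop <- founder_population(cfg, exact = TRUE)
    out[r, 1] <- allele_freqs(pop)
    for (t in seq_len(generations)) {
      pop <- advance_generation(pop, cfg, cfg$optimum_new)
      out[r, t + 1] <- allele_freqs(pop)
    }
  }
  out
}
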