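test_that("individual fitness combines trait distance and masked costs", {
  cfg <- sim_config(n_loci = 3, census_size = 10, effect_sizes = 1,
                    optimum_old = 0, optimum_new = 0, selection_width = 2,
                    cost_per_locus = c(0.5, 0.2, 0.1), cost_dominance = 0)
  # no beneficial alleles, optimum at 0: w = exp(0) = 1
  expect_equal(individual_fitness(c(0, 0, 0), c(0, 0, 0), cfg, 0), 1)
  # heterozygote with fully recessive cost is completely masked
  cfg1 <- sim_config(n_loci = 1, census_size = 10, effect_sizes = 1,
                     cost_per_locus = 0.5, cost_dominance = 0,
                     selection_width = 2)
  z_het <- 1  # additive heterozygote trait value
  expect_equal(individual_fitness(c(1), c(0), cfg1, optimum = z_het), 1)
  # homozygote expresses the full cost: w = 1 - c
  cfg2 <- sim_config(n_loci = 1, census_size = 10, effect_sizes = 1,
                     cost_per_locus = 0.2, cost_dominance = 0,
                     selection_width = 2)
  expect_equal(individual_fitness(c(1), c(1), cfg2, optimum = 2), 0.8)
  # partially dominant cost scales with h_c in the heterozygote
  cfg3 <- sim_config(n_loci = 1, census_size = 10, effect_sizes = 1,
                     cost_per_locus = 0.4, cost_dominance = 0.5,
                     selection_width = 2)
  expect_equal(individual_fitness(c(1), c(0), cfg3, optimum = 1), 0.8)
})

test_that("config validation rejects impossible parameter values", {
  expect_error(sim_config(n_loci = 2, cost_per_locus = 1), "cost")
  expect_error(sim_config(n_loci = 2, init_freqs = 1.5), "init_freqs")
  expect_error(sim_config(n_loci = 2, mix_proportion = 0), "mix_proportion")
  expect_error(sim_config(n_loci = 2, census_size = 1), "census_size")
  expect_error(sim_config(n_loci = 3, recomb_model = c(0.1, 0.7)),
               "recomb_model")
  expect_error(sim_config(n_loci = 2, effect_sizes = Inf), "finite")
})

test_that("a population with zero fitness everywhere goes extinct loudly", {
  cfg <- sim_config(n_loci = 1, census_size = 50, effect_sizes = 1,
                    init_freqs = 0, optimum_new = 1e6, selection_width = 1,
                    cost_per_locus = 0)
  pop <- founder_population(cfg)
  expect_error(advance_generation(pop, cfg, cfg$optimum_new), "extinct")
})

test_that("neutral evolution drifts without direction", {
  set.seed(101)
  traj <- wf_drift_trajectories(400, 200, 0.5, 5)
  dp <- traj[, 6] - traj[, 1]
  se <- sd(dp) / sqrt(length(dp))
  expect_lt(abs(mean(dp)), 3 * se)
})

test_that("directional selection tracks the deterministic diploid recursion", {
  # Gaussian trait fitness with the optimum far above the attainable trait
  # value acts like genic selection; compare each realized generation with a
  # one-step-ahead prediction from the exact HWE recursion at the same
  # frequency.
  omega <- sqrt(1000)
  theta <- 50
  cfg <- sim_config(n_loci = 1, census_size = 20000, effect_sizes = 1,
                    init_freqs = 0.1, optimum_new = theta,
                    selection_width = omega, cost_per_locus = 0)
  w <- exp(-((0:2) - theta)^2 / (2 * omega^2))
  set.seed(7)
  pop <- founder_population(cfg, exact = TRUE)
  err <- numeric(25)
  for (t in 1:25) {
    q_now <- allele_freqs(pop)
    pop <- advance_generation(pop, cfg, theta)
    err[t] <- abs(allele_freqs(pop) - det_selection_step(q_now, w))
  }
  expect_lt(max(err), 0.01)
})

test_that("admixture hits the expected mixture frequency and binomial moments", {
  set.seed(42)
  n <- 400
  imm <- exact_population(n, 0.8)
  rec <- exact_population(n, 0.2)
  draws <- replicate(500, {
    mx <- admix(imm, rec, m = 0.15, n = n)
    c(freq = unname(allele_freqs(mx)), frac = mean(mx$l1[, 1]))
  })
  expected <- 0.15 * 0.8 + 0.85 * 0.2
  se <- sd(draws["freq", ]) / sqrt(500)
  expect_lt(abs(mean(draws["freq", ]) - expected), 3 * se)
  # realized immigrant fraction: binomial moments m and m(1-m)/N
  frac <- draws["frac", ]
  expect_lt(abs(mean(frac) - 0.15), 3 * sd(frac) / sqrt(500))
  expect_lt(abs(var(frac) / (0.15 * 0.85 / n) - 1), 0.35)
})

test_that("admixing identical populations is symmetric", {
  set.seed(43)
  pop <- exact_population(300, 0.4)
  f <- replicate(200, unname(allele_freqs(admix(pop, pop, m = 0.5))))
  expect_lt(abs(mean(f) - 0.4), 3 * sd(f) / sqrt(200))
})

test_that("admixture validates its inputs", {
  pop <- exact_population(50, 0.5)
  expect_error(admix(pop, pop, m = 1.2), "m must lie")
  pop2 <- exact_population(50, c(0.5, 0.5))
  expect_error(admix(pop, pop2, m = 0.15), "locus indexing")
})

test_that("Pool-Seq sampling conserves depth and reproduces two-stage noise", {
  set.seed(11)
  # fixation: no sampling variance at all
  fixed <- exact_population(100, 1)
  ps <- pool_seq_sample(fixed, poolseq_config(coverage = 50))
  expect_equal(unname(ps[1, ]), c(50, 0))
  # fixed coverage model: every site sums to exactly the coverage
  pop <- exact_population(500, rep(0.5, 2000))
  ps <- pool_seq_sample(pop, poolseq_config(coverage = 50))
  expect_true(all(rowSums(ps) == 50))
  obs <- ps[, "beneficial"] / 50
  expect_lt(abs(mean(obs) - 0.5), 3 * sd(obs) / sqrt(2000))
  # sub-pooling adds the first sampling stage: compound variance of a
  # hypergeometric pool draw plus binomial reads
  psc <- poolseq_config(coverage = 50, pool_size = 100)
  ps2 <- pool_seq_sample(pop, psc)
  v_pool <- 0.25 / 200 * (1000 - 200) / (1000 - 1)
  v_expect <- v_pool + (0.25 + v_pool) / 50
  v_obs <- var(ps2[, "beneficial"] / 50)
  expect_lt(abs(v_obs / v_expect - 1), 0.2)
  expect_error(pool_seq_sample(exact_population(10, 0.5),
                               poolseq_config(pool_size = 20)),
               "pool_size")
})

test_that("Poisson coverage varies by site but counts stay consistent", {
  set.seed(12)
  pop <- exact_population(100, rep(0.5, 500))
  ps <- pool_seq_sample(pop, poolseq_config(coverage = 40,
                                            coverage_model = "poisson"))
  expect_gt(var(rowSums(ps)), 0)
  expect_true(all(ps >= 0))
  expect_lt(abs(mean(rowSums(ps)) - 40), 3 * sd(rowSums(ps)) / sqrt(500))
})

test_that("redundant architectures adapt through different locus subsets", {
  l <- 30
  cfg <- sim_config(n_loci = l, census_size = 200, init_freqs = 0.005,
                    optimum_new = 2 * l * 0.005 + 0.3 * l,
                    selection_width = sqrt(2 * l), cost_per_locus = 0.05)
  rising_set <- function(seed) {
    set.seed(seed)
    res <- adapt(founder_population(cfg), cfg, generations = 110)
    which(res$trajectory[111, ] - res$trajectory[1, ] > 0.3)
  }
  s1 <- rising_set(21)
  s2 <- rising_set(22)
  expect_gt(length(s1), 0)
  expect_gt(length(s2), 0)
  jaccard <- length(intersect(s1, s2)) / length(union(s1, s2))
  expect_lt(jaccard, 1)
})

test_that("an unmoved optimum produces no systematic allele-frequency rise", {
  l <- 50
  cfg <- sim_config(n_loci = l, census_size = 200, init_freqs = 0.2,
                    optimum_new = 2 * l * 0.2, optimum_old = 2 * l * 0.2,
                    selection_width = sqrt(5 * l), cost_per_locus = 0)
  set.seed(31)
  res <- adapt(founder_population(cfg), cfg, generations = 30)
  dp <- res$trajectory[31, ] - res$trajectory[1, ]
  expect_lt(abs(mean(dp)), 3 * sd(dp) / sqrt(l))
})

test_that("census size and haplotype encoding are preserved across generations", {
  cfg <- sim_config(n_loci = 10, census_size = 120, init_freqs = 0.3,
                    cost_per_locus = 0.05)
  set.seed(5)
  pop <- founder_population(cfg)
  for (i in 1:5) pop <- advance_generation(pop, cfg, cfg$optimum_new)
  expect_equal(nrow(pop$h1), 120)
  expect_true(all(pop$h1 %in% c(0, 1) & pop$h2 %in% c(0, 1)))
  expect_equal(pop$generation, 5L)
  f <- allele_freqs(pop)
  expect_true(all(f >= 0 & f <= 1))
})

test_that("linked recombination keeps adjacent loci correlated", {
  cfg <- sim_config(n_loci = 2, census_size = 400, init_freqs = 0.5,
                    effect_sizes = 0, cost_per_locus = 0,
                    selection_width = Inf,
                    recomb_model = 0.01)
  set.seed(9)
  n <- 400
  # start from perfect coupling: haplotypes all 11 or 00
  h <- matrix(rep(rbinom(n, 1, 0.5), 2), n, 2)
  h2 <- matrix(rep(rbinom(n, 1, 0.5), 2), n, 2)
  pop <- population_state(h, h2)
  for (i in 1:5) pop <- advance_generation(pop, cfg, 0)
  coupled <- mean(pop$h1[, 1] == pop$h1[, 2])
  expect_gt(coupled, 0.9)  # r = 0.01 over 5 generations barely decays
})
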