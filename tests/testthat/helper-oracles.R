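# Independent oracles used across tests.

# Deterministic diploid selection recursion under random mating (HWE):
# genotype fitnesses w = c(w0, w1, w2) for 0/1/2 copies of the allele.
det_selection_step <- function(q, w) {
  num <- q^2 * w[3] + q * (1 - q) * w[2]
  den <- q^2 * w[3] + 2 * q * (1 - q) * w[2] + (1 - q)^2 * w[1]
  num / den
}

det_selection_traj <- function(q0, w, generations) {
  q <- numeric(generations + 1)
  q[1] <- q0
  for (t in seq_len(generations)) q[t + 1] <- det_selection_step(q[t], w)
  q
}

# Closed-form Wright-Fisher drift variance after t generations at fixed p0.
wf_drift_var <- function(p0, n, t) {
  p0 * (1 - p0) * (1 - (1 - 1 / (2 * n))^t)
}

# Two-sample toy sync fixture used by the sync-io tests.
toy_sync_lines <- function() {
  c("sim1\t1000\tA\t10:0:40:0:0:0\t25:0:25:0:0:0",
    "sim1\t2000\tC\t0:0:50:0:0:0\t0:0:49:1:0:0",
    "sim2\t5\tG\t3:0:0:47:0:2\t0:0:0:50:0:0")
}

# A small population at exact allele frequencies, one column per locus.
exact_population <- function(n, freqs) {
  cfg <- sim_config(n_loci = length(freqs), census_size = n,
                    effect_sizes = 0, init_freqs = freqs,
                    cost_per_locus = 0, selection_width = Inf)
  founder_population(cfg, exact = TRUE)
}
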