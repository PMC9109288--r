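# pleiocost

Quantifying the fitness cost of pleiotropy from imbalanced admixture of
experimentally evolved populations.

## The problem

Adaptive alleles usually have side effects on phenotypes other than the
selected trait. The fitness cost of those side effects — the cost of
pleiotropy — is hard to measure trait by trait: any phenotype panel sees
only a few of the affected traits, and single-generation assays lack
power. `pleiocost` implements an integrative, fitness-level measurement
for evolve-and-resequence (E&R) experiments: mix two replicate
populations that adapted independently to the same environment at an
imbalanced ratio (15% *immigrant* : 85% *recipient*) and read the cost
off the asymmetric allele-frequency dynamics that follow.

The mechanism is dominance masking. After mixture, the immigrant
population's beneficial alleles are rare and sit mostly in heterozygotes,
so their (partially) recessive pleiotropic side effects are masked; the
recipient's beneficial alleles remain common and keep paying the full
cost. With stabilizing selection holding the mixed population at the
trait optimum, the decline of the costly common alleles is compensated by
a rise of the masked rare ones: immigrant-beneficial alleles rise,
recipient-beneficial alleles fall, and low-frequency alleles respond most.

## What the package provides

* An individual-based diploid Wright–Fisher simulator of the full
  two-phase experiment: polygenic adaptation to a shifted trait optimum
  under Gaussian stabilizing selection with per-locus pleiotropic costs
  whose heterozygous expression is set by a dominance coefficient
  (`h_c = 0` = fully recessive), followed by 15:85 admixture and
  Pool-Seq sampling with two-stage (pool + read) binomial noise
  (`run_experiment()`, `run_designated_experiment()`).
* Sync-level data handling: a PoPoolation2 sync reader/writer, BED-style
  interval masking with flanks, summed min-count biallelic SNP calling,
  and count-to-frequency conversion (`read_sync()`, `apply_masks()`,
  `call_snps()`, `frequencies()`).
* The inference chain: polarization of each SNP to the allele rising over
  the parental adaptation window, conditioning on presence and a strict
  frequency ceiling of 0.9, per-locus selection coefficients

      s_i = (2 / dt) * ln[ q_f (1 - q_b) / (q_b (1 - q_f)) ],

  mean frequency changes per analysis class with bootstrap intervals,
  the frequency-binned response with a permutation-tested rank
  correlation, and the cost of pleiotropy — the mean selective advantage
  revealed in the mixture, reported with a positive sign and compared
  with the realized parental selection coefficient
  (`polarize_to_rising()`, `condition_snps()`, `estimate_s()`,
  `cost_of_pleiotropy()`, `realized_vs_cost()`).
* Divergence utilities: Hudson-style pairwise pool F_ST, PCA of
  allele-frequency samples, min–max normalization (`fst_pairwise()`,
  `pca_frequencies()`, `minmax_normalize()`).

## Worked example

A desk-scale replica of the whole experiment — two parental populations
with disjoint selected-locus subsets, both 15:85 orderings mixed in
triplicate, 29 generations, 40x Pool-Seq, full inference — runs in a few
seconds:

```r
library(pleiocost)
rep <- run_replica(seed = 1)
print(rep)
#> Admixture replica (seed 1)
#>   SNPs: 60 polymorphic of 60 loci; immigrant class n = 279, recipient n = 279
#>   [pass        ] immigrant_vs_recipient_asymmetry = 0.0569 (imm 0.0207 [0.0004, 0.0405]; rec -0.0362 [-0.0573, -0.0154])
#>   [pass        ] negative_frequency_response_correlation = -0.7773 (rho -0.777, permutation p 0.0010)
#>   [pass        ] cost_below_realized_advantage = 0.4192 (cost 0.0247 [0.0126, 0.0373]; realized s 0.0589)
#>   [pass        ] pca_movement_toward_immigrant = 0.8069 (mean dist to immigrant founder: F1 4.950, late 3.995)
```

Reading the numbers: between F1 and F20 the immigrant-beneficial alleles
rose by 0.021 on average while the recipient-beneficial alleles fell by
0.036 (the masking asymmetry); the response is strongly
frequency-dependent (Spearman rho = -0.78, rarest alleles respond most);
the implied cost of pleiotropy, s = 0.025 per generation, is positive but
well below the realized parental selection coefficient of 0.059 (ratio
0.42) — a weak but clearly detectable pleiotropic load; and in PC space
the mixed populations move toward the immigrant founder (distance ratio
0.81). Setting `cost = 0` or `cost_dominance = 1` removes or reverses the
asymmetry, which is the control that ties the signal to recessive
pleiotropic costs.

The `analysis/` directory holds the numbered workflow over the same
functions — `01_simulate.R` (full two-phase simulation of 4 parental
replicates and 12 mixed populations, written as sync/truth/manifest
files), `02_analyze.R` (sync back in, full inference, tidy TSV tables),
`03_replica_checks.R` (the three cost regimes), and
`04_divergence_ordering.R` (F_ST and immigrant advantage versus
selected-set overlap) — each writing its tables under `results/`.

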