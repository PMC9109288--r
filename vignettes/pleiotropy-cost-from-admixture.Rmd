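---
title: "Measuring the cost of pleiotropy from imbalanced admixture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the cost of pleiotropy from imbalanced admixture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleiocost)
```

## The question and the experimental logic

Adaptive alleles rarely affect a single phenotype. When a beneficial allele
also perturbs other traits, the side effects impose a fitness cost — the
cost of pleiotropy — that is notoriously hard to measure, because any
single phenotype assay sees only a sliver of it. `pleiocost` implements an
integrative measurement that works at the level of fitness itself, using
experimental admixture between populations that adapted independently to
the same environment.

The logic: two replicate populations reach the same trait optimum using
*different* sets of loci. Mix them at an imbalanced ratio (15% "immigrant",
85% "recipient"). The immigrant population's beneficial alleles are now
rare, so they occur mostly in heterozygotes. If their pleiotropic side
effects are (partially) recessive, those side effects are masked in
heterozygotes, while the recipient population's beneficial alleles — still
common, often homozygous — continue to pay their full pleiotropic bill.
Because stabilizing selection holds the mixed population at the trait
optimum, the loss of the costly common alleles must be compensated by a
rise of the masked rare ones. The result is a measurable asymmetry:
immigrant-beneficial alleles rise after mixture while recipient-beneficial
alleles fall, with the response strongest for the rarest (best-masked)
alleles. The mean selective advantage revealed this way *is* the cost of
pleiotropy, with a positive sign by convention.

## The simulation model

Individuals are diploids with `L` biallelic loci. The quantitative trait is
`z = sum_i a_i g(d_i, genotype_i)`, where a genotype with 0/1/2 copies of
the beneficial allele contributes `0 / 2 d_i a_i / 2 a_i` (so `d = 0.5` is
additive). Fitness multiplies two terms:

* **Stabilizing selection**: `exp(-(z - theta)^2 / (2 omega^2))`, a
  Gaussian around the current trait optimum `theta` with width `omega`
  (trait units; `Inf` disables trait selection).
* **Pleiotropic load**: `prod_i (1 - c_i eta_i)`, where `c_i` is the
  per-locus cost carried by the beneficial allele and the exposure
  `eta_i` is 0, `h_c`, or 1 for 0, 1, or 2 copies. `h_c = 0` makes the
  cost fully recessive — completely masked in heterozygotes — which is
  the default, following the theoretical and empirical expectation that
  deleterious side effects are largely recessive while beneficial trait
  effects are (partially) dominant.

Generations are discrete Wright–Fisher steps at constant census `N`:
fitness-weighted sampling of distinct parent pairs, one recombinant
gamete per parent (free recombination by default; a linked mode with
per-interval crossover fractions is available), no new mutation —
adaptation uses standing variation only, as in an experiment founded from
wild-derived isofemale lines. Admixture draws the immigrant count
binomially around `m N`, reproducing the stochastic variation that arises
when mixed populations are physically assembled from finite fly samples.

Pool-Seq observation noise is two-stage: a pool of individuals is drawn
without replacement (whole-population pooling by default), then per-site
read counts are binomial at the pool frequency with fixed or
Poisson-distributed depth.

## What the inference chain computes

1. **Filtering** (`call_snps`, `apply_masks`): counts are summed across
   all samples; a site is kept iff exactly two nucleotide alleles reach
   the minimum count (5, inclusive). Sites with three qualifying alleles
   are dropped outright — the estimator is strictly biallelic and
   silently reducing to the top two would bias frequencies. Mask
   intervals (BED, 0-based half-open) are expanded by a 5-bp flank and
   remove records by position only; conversion between the 1-based sync
   convention and BED happens at exactly one boundary, inside
   `apply_masks`.
2. **Polarization** (`polarize_to_rising`): the beneficial allele of each
   SNP is the allele that did not fall between parental generations 0 and
   110. Exact ties break toward the lexicographically smaller base and
   are flagged; they carry no directional information and are excluded
   from coefficient summaries.
3. **Conditioning** (`condition_snps`): keep SNPs present at the
   adaptation endpoint (`q110 > 0`) and below 0.9 (strict) — the ceiling
   removes alleles already close to fixation, for which no further rise
   is observable.
4. **Selection coefficients** (`estimate_s`):
   `s = (2 / dt) * [logit(q_f) - logit(q_b)]`, the diploid codominant
   scaling (it recovers the homozygote advantage for genotype fitnesses
   `1, 1 + s/2, 1 + s`). Because the log-odds diverge at 0 and 1,
   frequencies are clamped at `1/(2 * coverage)` by default — half a
   read at the nominal depth — and clamped entries are flagged.
   Generation labels are explicit: F1 to F20 spans `dt = 19`
   generations, the parental adaptation window `dt = 110`.
5. **Headline statistics**: mean frequency change per analysis class with
   SNP-level percentile-bootstrap confidence intervals (SNPs sit in
   unknown linkage blocks, so analytic independence-based errors would
   overstate precision); the frequency-binned response with a Spearman
   correlation and permutation p-value; the cost of pleiotropy as the
   mean coefficient of the focal class over the early mixture window; and
   its ratio to the realized parental coefficient of the same parent's
   conditioned alleles.
6. **Divergence**: Hudson-style pool FST
   (`1 - Hw/Hb`, no within-pool sample-size terms, negative estimates
   truncated at zero and counted; a Nei-style variant is available for
   matching other pipelines), and PCA of centered, unscaled allele
   frequencies (variance scaling would up-weight rare alleles), with
   component signs canonicalized so results are deterministic.

Two class definitions coexist. The analysis classes used for the headline
statistics are "all alleles polarized in the immigrant parent" and
"... in the recipient parent" — the classes an admixture experiment can
actually track, since the true selection targets are unknown. The
exclusive four-way partition (`assign_origin`: immigrant-only,
recipient-only, shared-same-allele, shared-opposite) is attached to every
estimate for stratification; in simulated data, where every locus
segregates in both parents, the exclusive classes are nearly empty, and
the shared-same-allele class is exactly the high-starting-frequency class
that is counter-selected after mixture.

The cost of pleiotropy defaults to the immigrant focal class (the masked,
low-frequency class whose rise reveals the cost) with the positive-sign
convention; the recipient-side variant (sign-flipped) and a
mixed-minus-pure difference variant are implemented as named options,
because the verbal definition of the statistic can be read either way and
the package makes both readings available rather than guessing.

## What the generator emulates — and what it does not

The default configuration reproduces the study design: 1250 diploids per
population, 110 generations of adaptation, continuation to generations
120 and 130, both orderings of population pairs mixed 15:85 in
triplicate, mixture samples at F1/F20/F29, ~50x Pool-Seq coverage.
Synthetic loci are placed at `1000 * i` on one pseudo-chromosome with a
per-locus beneficial base recorded in a truth table.

Values the design does not fix were chosen once, on these grounds:

* **Founder frequencies** default to 0.05; the redundant-adaptation
  scenarios use 0.005 (rare standing variants) so that which loci escape
  drift early — and therefore which subset sweeps — differs between
  replicates, reproducing the observed heterogeneity of replicate
  responses.
* **Trait architecture**: equal effects `a = 1`, new optimum reachable by
  roughly a quarter to a half of the total additive capacity (genetic
  redundancy), `omega^2` of order `L` trait units squared, i.e. a few
  phenotypic standard deviations — strong enough that populations reach
  and then hold the optimum within the adaptation phase, as the
  phenotypic data show.
* **Cost**: `c = 0.05` per locus, fully recessive. This is the "weak but
  detectable" regime the measurement targets.

Two simulation entry points cover the two uses. `run_experiment()` runs
the full two-phase simulation; parental selected subsets then arise
stochastically, and with only tens of loci the realized parental contrast
(and hence the pooled asymmetry) varies between runs — at genome scale
the real experiment pools many thousands of SNPs, which a desk-scale run
cannot. `run_designated_experiment()` therefore constructs the
post-adaptation parents directly with designated (by default disjoint)
selected subsets at frequency 0.8 against a 0.05 background, which pins
the parental differentiation by design; `run_replica()` uses it by
default and exposes `parental_mode = "adaptive"` for the full two-phase
version. Problem sizes for the replica: census 300, 60 loci, coverage
40x, three mixture replicates of both pair orderings — about 280
class-level SNP measurements per class.

Features of real data deliberately *not* emulated: linked haplotype
blocks (loci are unlinked by default, so bootstrap intervals on real data
should use the block options), sequencing error and mapping artifacts
(the model starts at sync-level counts), new mutation, demographic change
and sex-specific selection. Passing tests therefore demonstrate the
statistical machinery and the dominance-masking mechanism, not robustness
to genomic confounders.

## Numerical and design notes

* All randomness flows from one master seed; per-replicate and
  per-mixture streams are derived deterministically (`derive_seed`), so
  adding a replicate or pair never perturbs existing ones, and a rerun is
  byte-identical including the emitted sync files.
* In the zero-cost control, the mixture shows a *small reversed*
  asymmetry rather than exactly none: under Gaussian stabilizing
  selection at the optimum, selection against trait variance pushes rare
  alleles down and common alleles up (variance purging). The masking
  signal must therefore be read as the immigrant excess over this
  baseline, and the package's null checks assert that the immigrant
  excess is not positive — not that it is exactly zero. A fully dominant
  cost (`h_c = 1`) actively reverses the asymmetry: a rare allele is
  nearly always carried (and expressed) while a common allele is mostly
  paired with itself, so rare costly alleles are purged faster — the
  mirror image of masking.
* The frequency–response correlation uses the F1 frequency both as the
  binning variable and as the start of the change, as the experimental
  analysis does; shared sampling noise therefore contributes a negative
  component to the correlation, which is why the zero-cost control of
  the *asymmetry* (not the correlation) is the decisive null.
* Monomorphic-in-both sites are skipped by FST (between-heterozygosity
  zero); reciprocally fixed sites give exactly 1.
* Degenerate inputs are handled explicitly: zero sequencing depth yields
  a flagged missing frequency; a bootstrap over identical values returns
  a degenerate interval; a single occupied frequency bin reports an
  undefined correlation while still returning the bins; an all-zero
  fitness vector stops with an extinction error rather than cycling.

## Limitations

The cost estimate is a lower bound tied to the masking mechanism: costs
of codominant or dominant side effects do not produce the asymmetry and
are invisible to this design. At desk scale the number of loci bounds the
precision of every class mean; directions are stable across seeds but
magnitudes fluctuate. Haplotype-block structure, which dominates real
E&R data, is only available through the linked recombination mode and is
not the default.
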