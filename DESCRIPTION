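Package: pleiocost
Title: Quantifying the Fitness Cost of Pleiotropy from Imbalanced
    Admixture of Experimentally Evolved Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and Pool-Seq inference for measuring the
    pleiotropic fitness cost carried by adaptive alleles. An
    individual-based diploid Wright-Fisher simulator models polygenic
    adaptation to a new trait optimum under Gaussian stabilizing
    selection, with per-locus pleiotropic costs whose expression is
    modulated by dominance, followed by imbalanced (15:85) admixture
    between independently adapted replicate populations and pooled
    sequencing at ~50x coverage. The inference stack reads and filters
    PoPoolation2 sync files, polarizes beneficial alleles from parental
    frequency trajectories, estimates per-locus selection coefficients
    from log-odds frequency changes, quantifies the cost of pleiotropy
    from the asymmetric post-admixture dynamics of immigrant versus
    recipient beneficial alleles, and computes pairwise pool FST and
    allele-frequency PCA.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
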