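#' Polarize SNPs to the allele rising in the parental population
#'
#' For each biallelic SNP the beneficial allele is defined as the allele
#' whose frequency did not decrease between parental generations 0 and 110
#' (`q110 - q0 >= 0`). Exact ties are broken deterministically toward the
#' lexicographically smaller base and flagged. SNPs with a missing frequency
#' at either generation are excluded (counted in attribute `n_excluded`).
#'
#' @param freq_gen0,freq_gen110 frequencies of the *major* allele (as
#'   returned by [call_snps()] / [frequencies()]) at the two generations.
#' @param alleles data.frame with columns `chrom`, `pos`, `major`, `minor`.
#' @param source_replicate label of the parental replicate.
#' @return A data.frame of class `polarized_snps` with columns `chrom`,
#'   `pos`, `beneficial_allele`, `q0`, `q110`, `source_replicate`, `tie`.
#' @export
polarize_to_rising <- function(freq_gen0, freq_gen110, alleles,
                               source_replicate = NA_character_) {
  stopifnot(length(freq_gen0) == nrow(alleles),
            length(freq_gen110) == nrow(alleles))
  ok <- !is.na(freq_gen0) & !is.na(freq_gen110)
  d <- freq_gen110 - freq_gen0
  rising_major <- d > 0 |
    (d == 0 & pmin(alleles$major, alleles$minor) == alleles$major)
  out <- data.frame(
    chrom = alleles$chrom,
    pos = alleles$pos,
    beneficial_allele = ifelse(rising_major, alleles$major, alleles$minor),
    q0 = ifelse(rising_major, freq_gen0, 1 - freq_gen0),
    q110 = ifelse(rising_major, freq_gen110, 1 - freq_gen110),
    source_replicate = source_replicate,
    tie = d == 0,
    stringsAsFactors = FALSE
  )[ok, ]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(!ok)
  class(out) <- c("polarized_snps", "data.frame")
  out
}

#' Condition polarized SNPs on presence and a frequency ceiling
#'
#' Keeps SNPs whose beneficial allele is present at generation 110
#' (`q110 > 0`) and below the ceiling (`q110 < max_freq`, strict). The
#' operation is idempotent; exclusion counts are attached as attribute
#' `excluded` (named `absent` and `high_freq`).
#'
#' @param snps a [polarize_to_rising()] result.
#' @param max_freq strict upper frequency bound (default 0.9).
#' @return The conditioned subset, same class and columns.
#' @export
condition_snps <- function(snps, max_freq = 0.9) {
  absent <- snps$q110 <= 0
  high <- snps$q110 >= max_freq
  out <- snps[!absent & !high, ]
  rownames(out) <- NULL
  attr(out, "excluded") <- c(absent = sum(absent), high_freq = sum(high))
  class(out) <- class(snps)
  out
}

#' Classify SNP origin from two parental polarizations
#'
#' Joins the polarized SNP sets of the immigrant and the recipient parent on
#' genomic coordinates and assigns each SNP to one of four classes:
#' `immigrant` (polarized only in the immigrant parent), `recipient`
#' (only in the recipient parent), `shared-same-allele` (same beneficial
#' allele in both -- the high-starting-frequency class selected in both
#' replicates), or `shared-opposite` (opposite alleles rising). The classes
#' partition the union of the two sets.
#'
#' @param snps_immigrant,snps_recipient [polarize_to_rising()] results (in
#'   practice after [condition_snps()]).
#' @return A data.frame with coordinates, per-parent beneficial alleles and
#'   frequencies (suffixes `_imm`, `_rec`), and `origin_class`.
#' @export
assign_origin <- function(snps_immigrant, snps_recipient) {
  m <- merge(snps_immigrant, snps_recipient, by = c("chrom", "pos"),
             all = TRUE, suffixes = c("_imm", "_rec"))
  in_imm <- !is.na(m$beneficial_allele_imm)
  in_rec <- !is.na(m$beneficial_allele_rec)
  m$origin_class <- ifelse(
    in_imm & !in_rec, "immigrant",
    ifelse(!in_imm & in_rec, "recipient",
           ifelse(m$beneficial_allele_imm == m$beneficial_allele_rec,
                  "shared-same-allele", "shared-opposite")))
  m[order(m$chrom, m$pos), , drop = FALSE]
}
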