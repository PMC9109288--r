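#' Per-locus selection coefficient from a frequency change
#'
#' Estimates the per-generation selection coefficient of a locus from its
#' start and end frequencies over `delta_t` generations as
#' \deqn{s = \frac{2}{\Delta t} \ln\frac{q_f (1 - q_b)}{q_b (1 - q_f)},}
#' i.e. twice the per-generation change in log-odds. The factor 2 makes the
#' estimator recover the homozygote advantage under diploid codominant
#' selection (genotype fitnesses 1, 1 + s/2, 1 + s). Because the log-odds
#' diverge at 0 and 1, frequencies are first clamped into
#' `[boundary_eps, 1 - boundary_eps]`; clamped entries are flagged. A
#' sensible default for Pool-Seq data is `boundary_eps = 1/(2 * coverage)`.
#'
#' @param q_b,q_f start and end frequencies in \[0, 1\] (vectorized).
#' @param delta_t number of generations between the two measurements (>= 1).
#' @param boundary_eps clamp margin in (0, 0.5).
#' @return A data.frame with columns `q_b`, `q_f`, `delta_t`, `s`,
#'   `clamped`.
#' @export
#' @examples
#' estimate_s(0.1, 0.2, 20)$s  # 0.1 * log(2.25) ~ 0.0811
estimate_s <- function(q_b, q_f, delta_t, boundary_eps = 0.01) {
  if (length(delta_t) != 1 || delta_t == 0) {
    stop("delta_t must be a single value >= 1")
  }
  stopifnot(delta_t >= 1, boundary_eps > 0, boundary_eps < 0.5)
  stopifnot(length(q_b) == length(q_f))
  if (any(q_b < 0 | q_b > 1 | q_f < 0 | q_f > 1, na.rm = TRUE)) {
    stop("frequencies must lie in [0, 1]")
  }
  clamp <- function(q) pmin(pmax(q, boundary_eps), 1 - boundary_eps)
  cb <- clamp(q_b)
  cf <- clamp(q_f)
  data.frame(
    q_b = q_b, q_f = q_f, delta_t = delta_t,
    s = (2 / delta_t) * (stats::qlogis(cf) - stats::qlogis(cb)),
    clamped = (cb != q_b) | (cf != q_f)
  )
}

boot_ci <- function(x, stat = mean, n_boot = 1000, conf = 0.95) {
  if (length(unique(x)) == 1) return(c(x[1], x[1]))
  bs <- vapply(seq_len(n_boot),
               function(i) stat(x[sample.int(length(x), replace = TRUE)]),
               numeric(1))
  unname(stats::quantile(bs, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
}

#' Mean polarized allele-frequency change with bootstrap CI
#'
#' Computes the mean of `freq_end - freq_start` over a SNP subset, with a
#' percentile bootstrap confidence interval over SNPs. SNP pairs with a
#' missing value are dropped.
#'
#' @param freq_start,freq_end matched frequency vectors of the beneficial
#'   alleles.
#' @param subset optional integer/logical index selecting the SNPs.
#' @param n_boot bootstrap resamples (default 1000).
#' @param conf confidence level.
#' @return A list with `mean`, `ci` (length 2), and `n`.
#' @export
mean_afc <- function(freq_start, freq_end, subset = NULL, n_boot = 1000,
                     conf = 0.95) {
  stopifnot(length(freq_start) == length(freq_end))
  if (!is.null(subset)) {
    freq_start <- freq_start[subset]
    freq_end <- freq_end[subset]
  }
  d <- freq_end - freq_start
  d <- d[!is.na(d)]
  if (length(d) == 0) stop("empty SNP subset")
  list(mean = mean(d), ci = boot_ci(d, mean, n_boot, conf), n = length(d))
}

#' Mean parental frequency change over the unmixed control window
#'
#' Negative control: the same computation as [mean_afc()], applied to the
#' continued (unmixed) parental populations over the wall-clock window
#' matching the mixture experiment (generations 110 to 130).
#'
#' @inheritParams mean_afc
#' @param freq_110,freq_130 parental beneficial-allele frequencies at the
#'   two continuation timepoints.
#' @return As [mean_afc()].
#' @export
control_afc <- function(freq_110, freq_130, subset = NULL, n_boot = 1000,
                        conf = 0.95) {
  mean_afc(freq_110, freq_130, subset = subset, n_boot = n_boot, conf = conf)
}

#' Frequency-binned allele-frequency change and frequency--response
#' correlation
#'
#' Bins SNPs by their starting frequency, reports the per-bin mean change,
#' count, and standard error, and quantifies the frequency dependence of the
#' response by the Spearman rank correlation between starting frequency and
#' change, with a permutation p-value (two-sided). Under recessive
#' pleiotropic costs the expected correlation is negative: low-frequency
#' beneficial alleles are better masked and respond more strongly.
#'
#' @param freq_start starting frequencies in \[0, 1\].
#' @param afc matched frequency changes.
#' @param bins number of equal-width bins on \[0, 1\], or an explicit vector
#'   of bin edges.
#' @param n_perm permutation count for the p-value.
#' @return A list of class `freq_bin_summary`: `bins` (data.frame
#'   `bin_lo`, `bin_hi`, `mean_afc`, `n`, `se`), `correlation`, `p_perm`,
#'   `n` (SNPs used).
#' @export
bin_by_start_frequency <- function(freq_start, afc, bins = 10,
                                   n_perm = 1000) {
  stopifnot(length(freq_start) == length(afc))
  ok <- !is.na(freq_start) & !is.na(afc)
  freq_start <- freq_start[ok]
  afc <- afc[ok]
  edges <- if (length(bins) == 1) seq(0, 1, length.out = bins + 1) else bins
  grp <- cut(freq_start, edges, include.lowest = TRUE, labels = FALSE)
  bin_df <- data.frame(
    bin_lo = edges[-length(edges)],
    bin_hi = edges[-1],
    mean_afc = vapply(seq_len(length(edges) - 1),
                      function(b) if (any(grp == b)) mean(afc[grp == b]) else NA_real_,
                      numeric(1)),
    n = vapply(seq_len(length(edges) - 1),
               function(b) sum(grp == b), integer(1)),
    se = vapply(seq_len(length(edges) - 1), function(b) {
      v <- afc[grp == b]
      if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
    }, numeric(1))
  )
  rho <- NA_real_
  p_perm <- NA_real_
  if (sum(bin_df$n > 0) >= 2 && stats::sd(freq_start) > 0 &&
      stats::sd(afc) > 0) {
    rx <- rank(freq_start)
    ry <- rank(afc)
    rho <- stats::cor(rx, ry)
    perm <- vapply(seq_len(n_perm),
                   function(i) stats::cor(rx, sample(ry)), numeric(1))
    p_perm <- (1 + sum(abs(perm) >= abs(rho))) / (n_perm + 1)
  }
  structure(list(bins = bin_df, correlation = rho, p_perm = p_perm,
                 n = length(afc)),
            class = "freq_bin_summary")
}

#' Cost of pleiotropy from post-admixture selection coefficients
#'
#' The cost of pleiotropy is measured as the mean selective (dis)advantage
#' revealed by the imbalanced mixture over the stated analysis window
#' (F1 to F20 by default in the pipeline), reported with a positive sign
#' convention: for the immigrant focal class (the low-frequency alleles
#' whose recessive costs are masked) the cost equals their mean fitness
#' advantage `mean(s)`; for the recipient focal class (costs expressed) it
#' equals `-mean(s)`. With `method = "mixed_minus_pure"` the mean of the
#' per-SNP difference between the mixed-population coefficient and the
#' coefficient of the same alleles in the continued pure population is used
#' instead, which removes any shared background response.
#'
#' @param estimates data.frame of selection estimates with columns `s` and
#'   `origin_class` (e.g. from the pipeline's per-window estimate tables).
#' @param focal_origin `"immigrant"` (default) or `"recipient"`.
#' @param method `"mixed"` (default) or `"mixed_minus_pure"`.
#' @param pure_estimates for `method = "mixed_minus_pure"`: data.frame with
#'   columns `chrom`, `pos`, `s` of the same alleles in the pure parental
#'   population over the matching window; `estimates` must then also carry
#'   `chrom`, `pos`.
#' @param n_boot,conf bootstrap parameters for the CI.
#' @return A list with `cost`, `ci`, `n`, `focal_origin`, `method`.
#' @export
cost_of_pleiotropy <- function(estimates,
                               focal_origin = c("immigrant", "recipient"),
                               method = c("mixed", "mixed_minus_pure"),
                               pure_estimates = NULL,
                               n_boot = 1000, conf = 0.95) {
  focal_origin <- match.arg(focal_origin)
  method <- match.arg(method)
  foc <- estimates[!is.na(estimates$origin_class) &
                     estimates$origin_class == focal_origin, , drop = FALSE]
  if (nrow(foc) == 0) stop("no SNPs in the focal origin class")
  sgn <- if (focal_origin == "immigrant") 1 else -1
  if (method == "mixed") {
    vals <- sgn * foc$s
  } else {
    if (is.null(pure_estimates)) {
      stop("mixed_minus_pure requires pure_estimates")
    }
    m <- merge(foc, pure_estimates[, c("chrom", "pos", "s")],
               by = c("chrom", "pos"), suffixes = c("", "_pure"))
    if (nrow(m) == 0) stop("no SNPs shared with pure_estimates")
    vals <- sgn * (m$s - m$s_pure)
  }
  vals <- vals[!is.na(vals)]
  list(cost = mean(vals), ci = boot_ci(vals, mean, n_boot, conf),
       n = length(vals), focal_origin = focal_origin, method = method)
}

#' Compare realized parental selection to the cost of pleiotropy
#'
#' Joins per-pair mean realized selection coefficients (parental adaptation
#' window, 0 to 110) with the per-pair cost-of-pleiotropy estimates from the
#' mixture window and reports their ratio. On data in the regime studied
#' here the cost is substantially smaller than the realized advantage
#' (ratio < 1).
#'
#' @param parental_estimates data.frame with columns `pair` and `s`
#'   (per-SNP realized coefficients, or already-aggregated means).
#' @param mixed_estimates data.frame with columns `pair` and `s` (per-SNP
#'   coefficients of the focal class in the mixture, positive-cost sign).
#' @return A data.frame with one row per pair: `pair`, `realized_s`,
#'   `cost`, `ratio`.
#' @export
realized_vs_cost <- function(parental_estimates, mixed_estimates) {
  pp <- sort(unique(parental_estimates$pair))
  pm <- sort(unique(mixed_estimates$pair))
  if (!identical(pp, pm)) stop("mismatched pair labels")
  agg <- function(df) tapply(df$s, df$pair, mean, na.rm = TRUE)
  realized <- agg(parental_estimates)
  cost <- agg(mixed_estimates)
  data.frame(pair = names(realized),
             realized_s = as.numeric(realized),
             cost = as.numeric(cost[names(realized)]),
             ratio = as.numeric(cost[names(realized)] / realized),
             row.names = NULL, stringsAsFactors = FALSE)
}
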