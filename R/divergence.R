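#' Pairwise pool FST between two samples
#'
#' Hudson-style estimator on pool allele frequencies:
#' per SNP, `FST = 1 - Hw / Hb` with within-sample heterozygosity
#' `Hw = (2 p1 (1 - p1) + 2 p2 (1 - p2)) / 2` and between-sample
#' heterozygosity `Hb = p1 (1 - p2) + p2 (1 - p1)`. Sites monomorphic for
#' the same allele in both samples (Hb = 0) are skipped; negative per-SNP
#' estimates are truncated at 0 and counted. A Nei-style variant
#' (`1 - Hs / Ht` with `Ht` from the mean frequency) is available for
#' matching other pipelines. The mean is unweighted across SNPs by default;
#' `weight_by_depth` weights each SNP by its minimum depth across the two
#' samples.
#'
#' @param freq_matrix SNP x sample frequency matrix (any allele's frequency;
#'   FST is invariant to allele labeling).
#' @param pair length-2 vector of column indices or names.
#' @param method `"hudson"` (default) or `"nei"`.
#' @param depth_matrix optional matching depth matrix, needed for
#'   `weight_by_depth`.
#' @param weight_by_depth logical, off by default.
#' @return A list of class `divergence_result`: `per_snp` (truncated per-SNP
#'   values, `NA` at skipped sites), `mean`, `n_used`, `n_truncated`,
#'   `method`.
#' @export
#' @examples
#' m <- cbind(a = 0.2, b = 0.8)
#' fst_pairwise(m, c("a", "b"))$mean  # 1 - 0.32/0.68 ~ 0.529
fst_pairwise <- function(freq_matrix, pair, method = c("hudson", "nei"),
                         depth_matrix = NULL, weight_by_depth = FALSE) {
  method <- match.arg(method)
  freq_matrix <- as.matrix(freq_matrix)
  stopifnot(length(pair) == 2)
  p1 <- freq_matrix[, pair[1]]
  p2 <- freq_matrix[, pair[2]]
  ok <- !is.na(p1) & !is.na(p2)
  if (method == "hudson") {
    hw <- p1 * (1 - p1) + p2 * (1 - p2)
    hb <- p1 * (1 - p2) + p2 * (1 - p1)
  } else {
    hw <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
    pbar <- (p1 + p2) / 2
    hb <- 2 * pbar * (1 - pbar)
  }
  usable <- ok & hb > 0
  fst <- rep(NA_real_, length(p1))
  fst[usable] <- 1 - hw[usable] / hb[usable]
  n_trunc <- sum(fst < 0, na.rm = TRUE)
  fst[!is.na(fst) & fst < 0] <- 0
  if (sum(usable) < 1) stop("no usable SNPs for FST")
  mean_fst <- if (weight_by_depth) {
    if (is.null(depth_matrix)) stop("weight_by_depth requires depth_matrix")
    w <- pmin(depth_matrix[, pair[1]], depth_matrix[, pair[2]])[usable]
    sum(fst[usable] * w) / sum(w)
  } else {
    mean(fst[usable])
  }
  structure(list(per_snp = fst, mean = mean_fst, n_used = sum(usable),
                 n_truncated = n_trunc, method = method),
            class = "divergence_result")
}

#' Mean FST for every pair of samples
#'
#' @param freq_matrix SNP x sample frequency matrix.
#' @param ... passed to [fst_pairwise()].
#' @return A symmetric matrix of mean FST values (0 on the diagonal).
#' @export
fst_all_pairs <- function(freq_matrix, ...) {
  k <- ncol(freq_matrix)
  out <- matrix(0, k, k, dimnames = list(colnames(freq_matrix),
                                         colnames(freq_matrix)))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      out[i, j] <- out[j, i] <- fst_pairwise(freq_matrix, c(i, j), ...)$mean
    }
  }
  out
}

#' PCA of allele-frequency samples
#'
#' Samples (columns of the frequency matrix) are projected onto principal
#' components after centering each SNP; no unit-variance scaling is applied,
#' following the convention for allele-frequency PCA (scaling would
#' up-weight rare alleles). SNPs with any missing sample are dropped
#' listwise and counted. Component signs are canonicalized so the
#' largest-magnitude loading of each component is positive, making results
#' deterministic.
#'
#' @param freq_matrix SNP x sample frequency matrix (>= 2 samples).
#' @param sample_labels optional data.frame of per-sample annotation
#'   (e.g. replicate, generation), bound to the coordinates.
#' @param n_components number of components to return.
#' @return A list of class `pca_result`: `coordinates` (data.frame with
#'   `sample`, label columns, `PC1..PCk`), `explained_variance` (full
#'   non-increasing vector of fractions), `loadings`, `n_dropped`.
#' @export
pca_frequencies <- function(freq_matrix, sample_labels = NULL,
                            n_components = 2) {
  freq_matrix <- as.matrix(freq_matrix)
  n_samp <- ncol(freq_matrix)
  if (n_samp < 2) stop("PCA needs at least 2 samples")
  if (n_components > n_samp - 1) {
    stop("more components requested than samples - 1")
  }
  complete <- stats::complete.cases(freq_matrix)
  x <- t(freq_matrix[complete, , drop = FALSE])
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pr$x))
  for (j in seq_len(k)) {
    i_max <- which.max(abs(pr$rotation[, j]))
    if (pr$rotation[i_max, j] < 0) {
      pr$rotation[, j] <- -pr$rotation[, j]
      pr$x[, j] <- -pr$x[, j]
    }
  }
  tot <- sum(pr$sdev^2)
  expl <- if (tot > 0) pr$sdev^2 / tot else rep(0, length(pr$sdev))
  coords <- data.frame(sample = colnames(freq_matrix) %||%
                         paste0("S", seq_len(n_samp)),
                       stringsAsFactors = FALSE)
  if (!is.null(sample_labels)) coords <- cbind(coords, sample_labels)
  coords <- cbind(coords, as.data.frame(pr$x[, seq_len(k), drop = FALSE]))
  structure(list(coordinates = coords,
                 explained_variance = expl,
                 loadings = pr$rotation[, seq_len(k), drop = FALSE],
                 n_dropped = sum(!complete)),
            class = "pca_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Min-max normalization to the unit interval
#'
#' Rescales `(x - min) / (max - min)` so the maximum maps to 1 and the
#' minimum to 0 (the convention used for cross-protocol fecundity
#' comparisons).
#'
#' @param values numeric vector with at least 2 distinct values.
#' @return The rescaled vector.
#' @export
minmax_normalize <- function(values) {
  rng <- range(values, na.rm = TRUE)
  if (!is.finite(diff(rng)) || diff(rng) == 0) {
    stop("min-max normalization undefined: all values equal")
  }
  (values - rng[1]) / diff(rng)
}
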