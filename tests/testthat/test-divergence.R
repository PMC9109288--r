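test_that("Hudson FST matches hand-computed closed forms", {
  # identical populations: no differentiation
  m <- cbind(a = c(0.2, 0.5, 0.9), b = c(0.2, 0.5, 0.9))
  expect_equal(fst_pairwise(m, c("a", "b"))$mean, 0)
  # reciprocally fixed differences: complete differentiation
  m2 <- cbind(a = c(1, 1), b = c(0, 0))
  expect_equal(fst_pairwise(m2, c("a", "b"))$mean, 1)
  # single intermediate SNP: 1 - 0.32 / 0.68
  m3 <- cbind(a = 0.2, b = 0.8)
  expect_equal(fst_pairwise(m3, c("a", "b"))$mean, 1 - 0.32 / 0.68,
               tolerance = 1e-12)
  # Nei-style variant on the same SNP: 1 - 0.32 / 0.5
  expect_equal(fst_pairwise(m3, c("a", "b"), method = "nei")$mean,
               1 - 0.32 / 0.5, tolerance = 1e-12)
})

test_that("FST is symmetric, bounded, and skips uninformative sites", {
  set.seed(6)
  m <- cbind(a = runif(50), b = runif(50))
  f_ab <- fst_pairwise(m, c("a", "b"))
  f_ba <- fst_pairwise(m, c("b", "a"))
  expect_equal(f_ab$mean, f_ba$mean)
  expect_true(all(f_ab$per_snp >= 0 & f_ab$per_snp <= 1, na.rm = TRUE))
  # sites monomorphic for the same allele in both samples are skipped
  mono <- cbind(a = c(0, 1, 0.3), b = c(0, 1, 0.6))
  expect_equal(fst_pairwise(mono, c("a", "b"))$n_used, 1)
  expect_error(fst_pairwise(cbind(a = 0, b = 0), c("a", "b")), "usable")
  # allele relabeling (p -> 1 - p in both samples) leaves FST unchanged
  expect_equal(fst_pairwise(1 - m, c("a", "b"))$mean, f_ab$mean)
})

test_that("all-pairs FST matrix is symmetric with a zero diagonal", {
  set.seed(7)
  m <- matrix(runif(60), 20, 3, dimnames = list(NULL, c("x", "y", "z")))
  fm <- fst_all_pairs(m)
  expect_equal(fm, t(fm))
  expect_equal(diag(fm), c(x = 0, y = 0, z = 0))
})

test_that("PCA of frequencies is centered, affine, and reconstructable", {
  # identical samples collapse to the origin
  m <- cbind(a = c(0.2, 0.8, 0.5), b = c(0.2, 0.8, 0.5))
  res <- pca_frequencies(m, n_components = 1)
  expect_equal(res$coordinates$PC1, c(0, 0))
  # a midpoint sample projects to the midpoint on PC1
  set.seed(8)
  a <- runif(100)
  b <- runif(100)
  m3 <- cbind(A = a, B = b, C = (a + b) / 2)
  res3 <- pca_frequencies(m3, n_components = 2)
  expect_equal(res3$coordinates$PC1[3],
               mean(res3$coordinates$PC1[1:2]), tolerance = 1e-8)
  # explained variance fractions are non-increasing and sum to <= 1
  expect_true(all(diff(res3$explained_variance) <= 1e-12))
  expect_lte(sum(res3$explained_variance), 1 + 1e-12)
  # full-rank projection reconstructs the centered matrix
  pr <- stats::prcomp(t(m3), center = TRUE, scale. = FALSE)
  rec <- pr$x %*% t(pr$rotation)
  centered <- sweep(t(m3), 2, colMeans(t(m3)))
  expect_equal(unname(rec), unname(centered), tolerance = 1e-10)
  expect_error(pca_frequencies(m3, n_components = 3), "components")
})

test_that("PCA drops SNPs with missing samples and counts them", {
  m <- cbind(a = c(0.1, NA, 0.4, 0.6), b = c(0.2, 0.5, 0.4, 0.9),
             c = c(0.3, 0.1, 0.2, 0.8))
  res <- pca_frequencies(m, n_components = 1)
  expect_equal(res$n_dropped, 1L)
})

test_that("min-max normalization maps the range onto [0, 1] exactly", {
  expect_equal(minmax_normalize(c(10, 30, 20)), c(0, 1, 0.5))
  expect_equal(minmax_normalize(c(0, 1)), c(0, 1))
  set.seed(9)
  x <- rnorm(20)
  nx <- minmax_normalize(x)
  expect_equal(max(nx), 1)
  expect_equal(min(nx), 0)
  expect_error(minmax_normalize(c(2, 2, 2)), "equal")
})
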