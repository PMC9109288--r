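alleles_fixture <- function(n = 3) {
  data.frame(chrom = "s", pos = seq_len(n), major = rep("A", n),
             minor = rep("C", n), stringsAsFactors = FALSE)
}

test_that("polarization picks the rising allele and flips frequencies", {
  al <- alleles_fixture(3)
  pol <- polarize_to_rising(c(0.2, 0.7, 0.5), c(0.6, 0.3, 0.5), al,
                            source_replicate = "P1")
  expect_equal(pol$beneficial_allele, c("A", "C", "A"))
  expect_equal(pol$q0, c(0.2, 0.3, 0.5))
  expect_equal(pol$q110, c(0.6, 0.7, 0.5))
  expect_equal(pol$tie, c(FALSE, FALSE, TRUE))
  expect_true(all(pol$q110 - pol$q0 >= 0))
  expect_equal(pol$source_replicate, rep("P1", 3))
})

test_that("ties break toward the lexicographically smaller base", {
  al <- data.frame(chrom = "s", pos = 1L, major = "T", minor = "G",
                   stringsAsFactors = FALSE)
  pol <- polarize_to_rising(0.4, 0.4, al)
  expect_equal(pol$beneficial_allele, "G")
  expect_equal(pol$q0, 0.6)
  expect_true(pol$tie)
})

test_that("SNPs with missing frequencies are excluded and counted", {
  al <- alleles_fixture(3)
  pol <- polarize_to_rising(c(0.2, NA, 0.3), c(0.6, 0.5, NA), al)
  expect_equal(nrow(pol), 1)
  expect_equal(attr(pol, "n_excluded"), 2L)
})

test_that("conditioning enforces presence and the strict frequency ceiling", {
  al <- alleles_fixture(4)
  pol <- polarize_to_rising(c(0.1, 0.1, 0.0, 0.1),
                            c(0.95, 0.9, 0.0, 0.89), al)
  kept <- condition_snps(pol, max_freq = 0.9)
  expect_equal(kept$pos, 4L)                 # 0.89 < 0.9 kept
  ex <- attr(kept, "excluded")
  expect_equal(unname(ex["high_freq"]), 2L)  # 0.95 and exactly 0.9 dropped
  expect_equal(unname(ex["absent"]), 1L)     # q110 = 0 dropped
  # idempotent
  again <- condition_snps(kept, max_freq = 0.9)
  expect_equal(again$pos, kept$pos)
})

test_that("origin classes partition the union of the two polarized sets", {
  imm <- polarize_to_rising(c(0.1, 0.2, 0.3), c(0.5, 0.6, 0.7),
                            alleles_fixture(3))
  # recipient set shares pos 2 (same allele), pos 3 (opposite), adds pos 4
  rec <- data.frame(chrom = "s", pos = c(2L, 3L, 4L),
                    beneficial_allele = c("A", "C", "C"),
                    q0 = c(0.2, 0.1, 0.3), q110 = c(0.5, 0.6, 0.8),
                    source_replicate = "P2", tie = FALSE,
                    stringsAsFactors = FALSE)
  imm <- imm[imm$pos != 4, ]
  origin <- assign_origin(imm, rec)
  expect_equal(nrow(origin), 4)
  expect_equal(origin$origin_class[origin$pos == 1], "immigrant")
  expect_equal(origin$origin_class[origin$pos == 2], "shared-same-allele")
  expect_equal(origin$origin_class[origin$pos == 3], "shared-opposite")
  expect_equal(origin$origin_class[origin$pos == 4], "recipient")
  expect_false(anyNA(origin$origin_class))
})
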