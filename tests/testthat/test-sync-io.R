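test_that("sync lines parse into records with preserved column order", {
  s <- read_sync(toy_sync_lines())
  expect_equal(n_sites(s), 3)
  expect_equal(dim(s$counts)[2], 2)
  expect_equal(unname(s$counts[1, 1, "C"]), 40L)
  expect_equal(s$info$pos, c(1000L, 2000L, 5L))
  expect_equal(s$info$ref, c("A", "C", "G"))
  expect_equal(unname(s$counts[3, 1, "del"]), 2L)
})

test_that("empty input gives an empty collection", {
  s <- read_sync(character(0))
  expect_equal(n_sites(s), 0)
  expect_equal(write_sync(s), character(0))
})

test_that("malformed sync lines are reported with their line number", {
  expect_error(read_sync("sim1\t1100\tA\t1:2:3:4:5"),
               "line 1.*5 count fields")
  expect_error(read_sync("sim1\t10\tA\t1:2:3:4:5:x"), "line 1")
  inconsistent <- c(toy_sync_lines()[1], "sim1\t1100\tA\t1:2:3:4:5:6")
  expect_error(read_sync(inconsistent), "line 2.*inconsistent")
})

test_that("write/read round-trips sync text byte-identically", {
  lines <- toy_sync_lines()
  s <- read_sync(lines)
  expect_identical(write_sync(s), lines)
  expect_identical(write_sync(read_sync(write_sync(s))), lines)
})

test_that("masking removes flank-expanded intervals and nothing else", {
  s <- read_sync(c("sim1\t100\tA\t10:10:0:0:0:0",
                   "sim1\t107\tA\t10:10:0:0:0:0",
                   "sim1\t1\tA\t10:10:0:0:0:0"))
  masks <- mask_set("sim1", 95, 96)  # 0-based [95,96) + flank 5 => [90,101)
  out <- apply_masks(s, masks, flank = 5)
  expect_equal(out$info$pos, c(107L, 1L))
  expect_equal(attr(out, "n_removed"), 1L)
  # empty mask set is the identity
  id <- apply_masks(s, mask_set())
  expect_equal(n_sites(id), 3)
  expect_equal(attr(id, "n_removed"), 0L)
  # masking is idempotent and never touches counts
  twice <- apply_masks(out, masks, flank = 5)
  expect_identical(twice$counts, out$counts)
})

test_that("mask intervals merge to canonical non-overlapping form", {
  m <- mask_set(c("c1", "c1", "c2"), c(10, 15, 5), c(20, 30, 8))
  expect_equal(nrow(m), 2)
  expect_equal(m$end[m$chrom == "c1"], 30L)
  expect_error(mask_set("c1", 10, 10), "start < end")
})

test_that("SNP calling enforces the summed min-count and biallelic rules", {
  lines <- c("s\t1\tA\t30:0:2:0:0:0\t30:0:2:0:0:0",   # C total 4: dropped
             "s\t2\tA\t30:0:2:0:0:0\t30:0:3:0:0:0",   # C total 5: kept
             "s\t3\tA\t20:0:15:0:0:0\t20:0:15:10:0:0", # 3 alleles: dropped
             "s\t4\tA\t50:0:0:0:0:0\t50:0:0:0:0:0",   # monomorphic
             "s\t5\tA\t10:0:40:0:0:0\t25:0:25:0:0:0") # biallelic, A major
  calls <- call_snps(read_sync(lines), min_count = 5)
  expect_equal(calls$sync$info$pos, c(2L, 5L))
  expect_equal(calls$alleles$major, c("A", "C"))
  expect_equal(calls$alleles$minor, c("C", "A"))
  expect_equal(unname(calls$dropped["monomorphic"]), 2L)
  expect_equal(unname(calls$dropped["multiallelic"]), 1L)
  # calling again on the kept records changes nothing (idempotent)
  again <- call_snps(calls$sync, min_count = 5)
  expect_equal(again$sync$info, calls$sync$info)
})

test_that("frequencies use called nucleotides only and flag zero depth", {
  s <- read_sync(c("s\t1\tA\t10:0:40:0:0:0\t0:0:0:0:0:0",
                   "s\t2\tA\t10:0:10:0:5:25\t20:0:20:0:0:0"))
  fq <- frequencies(s, "C")
  expect_equal(unname(fq$freq[1, 1]), 0.8)  # 40 / 50
  expect_true(is.na(fq$freq[1, 2]))         # zero depth flagged, no crash
  expect_equal(attr(fq$freq, "n_missing"), 1L)
  expect_equal(unname(fq$freq[2, 1]), 0.5)  # N and del excluded: 10/20
  expect_equal(unname(fq$depth[2, 1]), 20L)
  expect_error(frequencies(s, "N"), "A, T, C, G")
})
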