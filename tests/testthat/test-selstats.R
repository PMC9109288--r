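test_that("the log-odds selection estimator matches its closed form", {
  expect_equal(estimate_s(0.3, 0.3, 10)$s, 0)
  expect_equal(estimate_s(0.1, 0.2, 20)$s, 0.1 * log(2.25), tolerance = 1e-12)
  # antisymmetry under swapping start and end
  expect_equal(estimate_s(0.2, 0.1, 20)$s, -estimate_s(0.1, 0.2, 20)$s)
  # relabeling alleles negates the coefficient
  expect_equal(estimate_s(1 - 0.1, 1 - 0.2, 20)$s, -estimate_s(0.1, 0.2, 20)$s)
  expect_error(estimate_s(0.1, 0.2, 0), "delta_t")
  expect_error(estimate_s(-0.1, 0.2, 10), "frequencies")
})

test_that("boundary frequencies are clamped and flagged, never infinite", {
  est <- estimate_s(c(0, 0.5), c(0.5, 1), 10, boundary_eps = 0.0125)
  expect_true(all(is.finite(est$s)))
  expect_equal(est$clamped, c(TRUE, TRUE))
  expect_false(estimate_s(0.3, 0.4, 10)$clamped)
})

test_that("the estimator recovers the true coefficient from deterministic
           codominant trajectories", {
  for (s_true in c(0.01, 0.05, 0.1)) {
    q <- det_selection_traj(0.1, c(1, 1 + s_true / 2, 1 + s_true), 20)
    s_hat <- estimate_s(q[1], q[21], 20)$s
    expect_lt(abs(s_hat - s_true) / s_true, 0.05)
  }
})

test_that("mean AFC handles degenerate and singleton subsets", {
  x <- c(0.2, 0.4, 0.6)
  res <- mean_afc(x, x)
  expect_equal(res$mean, 0)
  expect_equal(res$ci, c(0, 0))
  one <- mean_afc(0.30, 0.35)
  expect_equal(one$mean, 0.05)
  expect_equal(one$n, 1)
  expect_error(mean_afc(numeric(0), numeric(0)), "empty")
  set.seed(1)
  sub <- mean_afc(c(0.1, 0.2, 0.9), c(0.2, 0.4, 0.1), subset = 1:2)
  expect_equal(sub$mean, 0.15)
  expect_equal(sub$n, 2)
})

test_that("frequency bins summarize the response and detect monotone decay", {
  set.seed(2)
  q <- runif(200, 0.05, 0.95)
  res <- bin_by_start_frequency(q, -q, bins = 10, n_perm = 200)
  expect_equal(res$correlation, -1)
  expect_lt(res$p_perm, 0.05)
  expect_equal(sum(res$bins$n), 200)
  # identically zero response: flat bins, undefined correlation flagged
  zero <- bin_by_start_frequency(q, rep(0, 200), bins = 5, n_perm = 50)
  expect_true(all(zero$bins$mean_afc[zero$bins$n > 0] == 0))
  expect_true(is.na(zero$correlation))
  # a single occupied bin cannot support a correlation but bins are returned
  single <- bin_by_start_frequency(rep(0.5, 20), rnorm(20, 0, 0.01),
                                   bins = 4, n_perm = 50)
  expect_true(is.na(single$correlation))
  expect_equal(nrow(single$bins), 4)
})

test_that("cost of pleiotropy respects focal class and sign convention", {
  est <- data.frame(chrom = "s", pos = 1:6,
                    s = c(0.02, 0.04, 0.03, -0.05, -0.01, 0.2),
                    origin_class = c("immigrant", "immigrant", "immigrant",
                                     "recipient", "recipient",
                                     "shared-same-allele"))
  set.seed(3)
  imm <- cost_of_pleiotropy(est, "immigrant", n_boot = 200)
  expect_equal(imm$cost, 0.03)
  expect_equal(imm$n, 3)
  rec <- cost_of_pleiotropy(est, "recipient", n_boot = 200)
  expect_equal(rec$cost, 0.03)  # sign-flipped to the positive convention
  zero <- cost_of_pleiotropy(transform(est, s = 0), "immigrant", n_boot = 50)
  expect_equal(zero$cost, 0)
  expect_error(cost_of_pleiotropy(est[0, ], "immigrant"), "focal")
})

test_that("mixed-minus-pure variant subtracts the background response", {
  mixed <- data.frame(chrom = "s", pos = 1:3, s = c(0.05, 0.07, 0.06),
                      origin_class = "immigrant")
  pure <- data.frame(chrom = "s", pos = 1:3, s = c(0.01, 0.02, 0.03))
  set.seed(4)
  res <- cost_of_pleiotropy(mixed, "immigrant", method = "mixed_minus_pure",
                            pure_estimates = pure, n_boot = 100)
  expect_equal(res$cost, 0.04)
  expect_error(cost_of_pleiotropy(mixed, "immigrant",
                                  method = "mixed_minus_pure"),
               "pure_estimates")
})

test_that("realized-versus-cost comparison aligns pairs and computes ratios", {
  par_est <- data.frame(pair = rep(c("A", "B"), each = 3),
                        s = c(0.06, 0.05, 0.07, 0.04, 0.05, 0.03))
  mix_est <- data.frame(pair = rep(c("A", "B"), each = 2),
                        s = c(0.02, 0.01, 0.01, 0.02))
  res <- realized_vs_cost(par_est, mix_est)
  expect_equal(res$ratio, res$cost / res$realized_s)
  expect_true(all(res$ratio < 1))
  # identical inputs give ratio exactly 1
  same <- realized_vs_cost(par_est, par_est)
  expect_equal(same$ratio, c(1, 1))
  expect_error(realized_vs_cost(par_est,
                                transform(mix_est, pair = "C")),
               "mismatched")
})

test_that("the parental control window reports zero change when nothing moved", {
  q <- c(0.2, 0.5, 0.8)
  res <- control_afc(q, q)
  expect_equal(res$mean, 0)
  # fixed loci cannot move either
  fixed <- control_afc(c(1, 1), c(1, 1))
  expect_equal(fixed$mean, 0)
})
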