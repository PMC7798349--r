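test_that("Fisher z transform and difference test match closed forms", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.9), 0.5 * log(1.9 / 0.1), tolerance = 1e-12)
  expect_equal(fisher_z(0.9), 1.4722, tolerance = 1e-4)
  expect_equal(fisher_z(-0.6), -fisher_z(0.6))
  expect_warning(z1 <- fisher_z(1), "clamped")
  expect_true(is.finite(z1))

  same <- diff_test_fisher(0.5, 6, 0.5, 6)
  expect_equal(same$p_value, 1)
  res <- diff_test_fisher(0.9, 6, 0.0, 6)
  expect_equal(res$stat, 1.803, tolerance = 1e-3)
  expect_equal(res$p_value, 0.071, tolerance = 1e-2)
  swapped <- diff_test_fisher(0.0, 6, 0.9, 6)
  expect_equal(swapped$stat, -res$stat)
  expect_equal(swapped$p_value, res$p_value)
  expect_error(diff_test_fisher(0.5, 3, 0.2, 6), "n >= 4")
})

test_that("permutation difference p equals brute force over all splits", {
  withr::with_seed(81, {
    x <- rnorm(6); y <- rnorm(6)
    same <- diff_test_permutation(x, y, x, y)
    expect_equal(same$p_value, 1)
    expect_equal(same$delta, 0)

    for (i in 1:8) {
      n1 <- sample(4:6, 1); n2 <- sample(4:6, 1)
      mk <- function(n) if (i %% 2) rnorm(n) else sample(0:2, n, replace = TRUE)
      x1 <- mk(n1); y1 <- mk(n1); x2 <- mk(n2); y2 <- mk(n2)
      res <- diff_test_permutation(x1, y1, x2, y2)
      expect_equal(res$p_value, oracle_diff_p(x1, y1, x2, y2))
      expect_equal(res$n_perm, choose(n1 + n2, n1))
    }
  })
})

test_that("a strong group-specific correlation shifts the difference p downward", {
  # at n = 6+6 the fully-enumerated null of |delta rho*| is wide, so even a
  # near-perfect treatment-only coupling gives median p around 0.1; the
  # attainable signature is a strong enrichment of small p relative to the
  # 5% nominal rate, not near-zero p
  withr::with_seed(82, {
    ps <- replicate(30, {
      z <- rnorm(6)
      x2 <- z + rnorm(6, 0, 0.15)          # treatment: tightly coupled
      y2 <- z + rnorm(6, 0, 0.15)
      diff_test_permutation(rnorm(6), rnorm(6), x2, y2)$p_value
    })
  })
  expect_lt(median(ps), 0.25)
  expect_gt(mean(ps <= 0.05), 0.10)
})

test_that("difference networks are empty for identical records and full at alpha 1", {
  withr::with_seed(83, {
    vals <- matrix(rlnorm(12 * 10, 3, 0.8), nrow = 12)
  })
  ft <- tiny_table(vals, kind = "concentrations")
  recs_c <- all_pairs_correlation(ft, "control")
  recs_b <- all_pairs_correlation(ft, "berberine")

  dc_same <- suppressWarnings(diff_correlation_records(recs_c, recs_c))
  expect_equal(nrow(difference_network(dc_same, alpha = 0.01)$edges), 0)
  expect_true(all(dc_same$p == 1))

  dc <- suppressWarnings(diff_correlation_records(recs_c, recs_b))
  expect_equal(nrow(difference_network(dc, alpha = 1)$edges), nrow(dc))
  expect_true(all(abs(dc$delta) <= 2))

  # mismatched universes are refused with the difference listed
  expect_error(diff_correlation_records(recs_c, recs_b[-1, ]),
               "different feature pairs")
})

test_that("differential_correlations routes degenerate correlations to permutation", {
  withr::with_seed(84, {
    vals <- matrix(rlnorm(12 * 6, 3, 0.8), nrow = 12)
    vals[1:6, 1] <- 1:6        # control: feature 1 monotone in feature 2
    vals[1:6, 2] <- (1:6)^2
  })
  ft <- tiny_table(vals, kind = "concentrations")
  dc <- suppressWarnings(differential_correlations(ft, method = "fisher_z"))
  expect_equal(nrow(dc), choose(6, 2))
  r12 <- dc[dc$feature_i == "f1" & dc$feature_j == "f2", ]
  expect_equal(r12$rho_control, 1)
  expect_equal(r12$method, "permutation") # Fisher z diverges at |rho| = 1
  expect_true(all(dc$p > 0 & dc$p <= 1))
  # the permutation method agrees with the per-pair function
  dcp <- differential_correlations(ft, method = "permutation")
  ctl <- filter_group(ft, "control"); trt <- filter_group(ft, "berberine")
  one <- diff_test_permutation(ctl$values[, "f3"], ctl$values[, "f4"],
                               trt$values[, "f3"], trt$values[, "f4"])
  expect_equal(dcp$p[dcp$feature_i == "f3" & dcp$feature_j == "f4"],
               one$p_value)
})
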