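test_that("rho matches the closed form and the standard implementation", {
  expect_equal(spearman_rho(1:5, c(2, 4, 6, 8, 10)), 1)
  expect_equal(spearman_rho(1:5, 5:1), -1)
  # hand evaluation: d = (1,-1,1,-1,1,-1)... sum d^2 = 6
  expect_equal(spearman_rho(1:6, c(2, 1, 4, 3, 6, 5)), 1 - 36 / 210)
  withr::with_seed(71, {
    for (i in 1:20) {
      n <- sample(4:9, 1)
      x <- if (i %% 2) rnorm(n) else sample(0:3, n, replace = TRUE)
      y <- if (i %% 3) rnorm(n) else sample(0:3, n, replace = TRUE)
      if (sd(x) == 0 || sd(y) == 0) next
      expect_equal(spearman_rho(x, y), cor(x, y, method = "spearman"))
    }
  })
  expect_true(is.na(spearman_rho(rep(1, 5), 1:5)))
})

test_that("exact p equals brute-force enumeration over all n! permutations", {
  withr::with_seed(72, {
    for (i in 1:30) {
      n <- sample(4:7, 1)
      x <- if (i %% 2) rnorm(n) else sample(0:2, n, replace = TRUE)
      y <- if (i %% 3) rnorm(n) else sample(0:2, n, replace = TRUE)
      if (sd(x) == 0 || sd(y) == 0) next
      expect_equal(spearman_pvalue(x, y, method = "exact"),
                   oracle_spearman_p(x, y))
    }
  })
  # perfectly monotone untied n = 6: only identity and reversal reach |rho| = 1
  expect_equal(spearman_pvalue(1:6, c(3, 4, 9, 12, 40, 41)), 2 / 720)
  expect_error(spearman_pvalue(1:10, 10:1, method = "exact"), "t_approx")
  expect_error(spearman_pvalue(rep(1, 5), 1:5), "constant")
  # p never exceeds 1 and the t approximation is sane at larger n
  expect_lte(spearman_pvalue(1:20, rnorm(20), method = "t_approx"), 1)
})

test_that("all-pairs correlation covers every pair once, order-independently", {
  withr::with_seed(73, {
    vals <- matrix(rlnorm(12 * 21, 3, 1), nrow = 12)
  })
  colnames(vals) <- paste0("f", seq_len(ncol(vals)))
  ft <- tiny_table(vals, kind = "concentrations")
  rec <- all_pairs_correlation(ft, "control")
  expect_equal(nrow(rec), choose(21, 2))
  expect_true(all(rec$feature_i < rec$feature_j))
  expect_true(all(rec$n == 6))
  expect_true(all(rec$p > 0 & rec$p <= 1))

  # permuting feature order changes nothing
  perm <- sample(ncol(vals))
  ft2 <- tiny_table(vals[, perm, drop = FALSE], kind = "concentrations")
  rec2 <- all_pairs_correlation(ft2, "control") |>
    dplyr::arrange(feature_i, feature_j)
  expect_equal(as.data.frame(rec2), as.data.frame(rec), tolerance = 1e-12)

  # exact p agrees with the single-pair path
  k <- sample(nrow(rec), 5)
  for (r in k) {
    i <- rec$feature_i[r]; j <- rec$feature_j[r]
    ctl <- filter_group(ft, "control")
    expect_equal(rec$p[r],
                 spearman_pvalue(ctl$values[, i], ctl$values[, j]))
    expect_equal(rec$rho[r],
                 spearman_rho(ctl$values[, i], ctl$values[, j]))
  }

  # constant features are skipped and reported
  vals3 <- vals
  colnames(vals3) <- paste0("f", seq_len(ncol(vals3)))
  vals3 <- cbind(vals3, constant = 5)
  ft3 <- tiny_table(vals3, kind = "concentrations")
  expect_message(rec3 <- all_pairs_correlation(ft3, "control"), "constant")
  expect_equal(nrow(rec3), choose(21, 2))
  expect_identical(attr(rec3, "skipped_features"), "constant")
})
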