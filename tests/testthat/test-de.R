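test_that("TMM factors behave as a scaling normalization", {
  withr::with_seed(31, {
    base <- rnbinom(500, mu = rlnorm(500, 4, 1), size = 10) + 1L
  })
  identical_libs <- matrix(rep(base, 4), ncol = 4)
  nf <- normalize_counts(identical_libs)
  expect_equal(nf$factors$tmm_factor, rep(1, 4), tolerance = 1e-9)

  # doubling every count of one library leaves its composition, hence its
  # TMM factor, unchanged
  doubled <- identical_libs; doubled[, 2] <- doubled[, 2] * 2L
  nf2 <- normalize_counts(doubled)
  expect_equal(nf2$factors$tmm_factor, rep(1, 4), tolerance = 1e-9)

  withr::with_seed(32, {
    m <- matrix(rnbinom(2000 * 6, mu = rep(rlnorm(2000, 4, 1), 6), size = 5),
                ncol = 6)
    m[1:60, 4:6] <- m[1:60, 4:6] * 6L
  })
  nf3 <- normalize_counts(m)
  expect_equal(exp(mean(log(nf3$factors$tmm_factor))), 1, tolerance = 1e-12)
  # independent implementation of the same normalization
  ref <- edgeR::calcNormFactors(m, method = "TMM")
  expect_equal(nf3$factors$tmm_factor, unname(ref), tolerance = 1e-3)

  bad <- m; bad[, 3] <- 0L
  expect_error(normalize_counts(bad), "all-zero sample")
})

test_that("log2 fold changes are group mean differences with antisymmetry", {
  norm <- rbind(g1 = log2(c(8, 8, 8, 2, 2, 2)), g2 = log2(c(4, 4, 4, 4, 4, 4)))
  groups <- c(rep("berberine", 3), rep("control", 3))
  lfc <- log2_fold_change(norm, groups)
  expect_equal(unname(lfc), c(2, 0))
  flipped <- log2_fold_change(norm, rev(groups))
  expect_equal(unname(flipped), -unname(lfc))
})

test_that("permutation t p-values match brute-force enumeration of splits", {
  withr::with_seed(41, {
    m <- matrix(rnorm(8 * 12, mean = 8), nrow = 8)
  })
  rownames(m) <- paste0("g", 1:8)
  groups <- rep(c("control", "berberine"), each = 6)
  res <- de_test(m, groups, method = "perm_t")
  sel <- combn(12, 6)
  for (g in 1:8) {
    t_obs <- abs(unname(t.test(m[g, 1:6], m[g, 7:12])$statistic))
    t_all <- apply(sel, 2, function(ix) {
      abs(unname(t.test(m[g, ix], m[g, -ix])$statistic))
    })
    expect_equal(res$p_value[g], mean(t_all >= t_obs - 1e-12))
  }
  # constant gene is flagged with p = 1
  m2 <- rbind(m, const = rep(3, 12))
  res2 <- de_test(m2, groups, method = "perm_t")
  expect_equal(res2$p_value[res2$gene_id == "const"], 1)
  expect_true(res2$constant[res2$gene_id == "const"])
  expect_error(de_test(m[, 1:5], c(rep("control", 2), rep("berberine", 3)),
                       method = "perm_t"), "at least 3")
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_fdr(0.037), 0.037)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  withr::with_seed(51, {
    p <- runif(50)^2
    q <- bh_fdr(p)
    expect_true(all(q >= p - 1e-12))
    expect_true(all(q > 0 & q <= 1))
    # order-preserving
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  })
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
})

test_that("DE selection applies the fold-change and p thresholds", {
  res <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    log2fc = c(0.5, 2.0, -1.2, 0.59),
    p = c(0.001, 0.049, 0.02, 0.2)
  )
  kept <- filter_de(res)
  expect_identical(kept$gene_id, c("b", "c")) # |lfc| > 0.58 AND p < 0.05
  expect_equal(nrow(filter_de(res[0, ])), 0)
})

test_that("planted fold changes are recovered with small bias", {
  withr::with_seed(61, {
    n_genes <- 300
    mu <- rlnorm(n_genes, 4.6, 1)
    lfc_true <- rep(0, n_genes)
    lfc_true[1:30] <- rep(c(1, -1, 2, -2), length.out = 30)
    groups <- rep(c("control", "berberine"), each = 6)
    m <- sapply(seq_len(12), function(s) {
      mult <- if (groups[s] == "berberine") 2^lfc_true else rep(1, n_genes)
      rnbinom(n_genes, mu = mu * mult, size = 10)
    })
  })
  rownames(m) <- paste0("g", seq_len(nrow(m)))
  de <- run_de(m, groups, method = "perm_t", seed = 1)
  planted <- de$log2fc[1:30]
  expect_lt(abs(mean(planted - lfc_true[1:30])), 0.25)
  # strong effects are detected with high power
  strong <- abs(lfc_true) == 2
  expect_gt(mean(de$p[strong] < 0.05), 0.8)
})
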