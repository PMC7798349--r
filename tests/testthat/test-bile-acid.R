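test_that("internal-standard quantitation does the unit arithmetic", {
  expect_equal(quantify_from_is(1000, 1000, 100, 0.010), 10)
  expect_equal(quantify_from_is(2000, 1000, 100, 0.010), 20)
  expect_equal(quantify_from_is(0, 1000, 100, 0.010), 0)
  expect_error(quantify_from_is(10, 0), "internal standard")
  expect_error(quantify_from_is(-1, 10), "negative")
  expect_error(quantify_from_is(10, 10, sample_mass = 0), "positive")

  # linear in area, inverse-linear in mass (random inputs)
  withr::with_seed(42, {
    for (i in 1:20) {
      a <- runif(1, 10, 1e5); is <- runif(1, 100, 1e5)
      m <- runif(1, 0.001, 0.5); k <- runif(1, 0.5, 4)
      expect_equal(quantify_from_is(k * a, is, 100, m),
                   k * quantify_from_is(a, is, 100, m))
      expect_equal(quantify_from_is(a, is, 100, k * m),
                   quantify_from_is(a, is, 100, m) / k)
    }
  })
})

test_that("totals and class summaries conserve bile acid mass", {
  conc <- matrix(c(1.0, 0.29, 0, 0,
                   0.5, 0.1, 0.2, 0.02), nrow = 2, byrow = TRUE)
  panel <- tiny_panel(conc,
                      conjugation = c("unconjugated", "taurine", "taurine", "glycine"),
                      origin = c("primary", "primary", "secondary", "secondary"),
                      sulfated = c(FALSE, FALSE, FALSE, TRUE))
  tot <- total_bile_acids(panel)
  expect_equal(sort(tot$total), sort(c(1.29, 0.82)))

  for (by in c("conjugation", "origin", "sulfated")) {
    cls <- ba_class_summary(panel, by)
    per_sample <- tapply(cls$total, cls$sample_id, sum)
    expect_equal(as.numeric(per_sample[tot$sample_id]), tot$total)
  }

  # a panel of only conjugates has zero unconjugated total
  conj_only <- tiny_panel(matrix(c(1, 2, 3, 4), 2),
                          conjugation = c("taurine", "taurine"),
                          origin = c("primary", "primary"),
                          sulfated = c(FALSE, FALSE))
  cs <- ba_class_summary(conj_only, "conjugation")
  expect_false("unconjugated" %in% cs$class)
  expect_error(ba_class_summary(panel, "nonsense"))

  # all-zero sample total is 0
  zpanel <- tiny_panel(matrix(c(0, 0, 1, 2), 2, byrow = TRUE),
                       conjugation = c("unconjugated", "unconjugated"),
                       origin = c("primary", "primary"),
                       sulfated = c(FALSE, FALSE))
  expect_equal(min(total_bile_acids(zpanel)$total), 0)
})

test_that("exact Mann-Whitney matches full enumeration, including ties", {
  res <- compare_groups(c(1, 2, 3), c(4, 5, 6), test = "mann_whitney_exact")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1) # 2 of the C(6,3)=20 assignments are as extreme

  same <- compare_groups(c(1, 2, 3), c(1, 2, 3), test = "mann_whitney_exact")
  expect_equal(same$p_value, 1)

  withr::with_seed(7, {
    for (i in 1:25) {
      n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
      x <- if (i %% 2) rnorm(n1) else sample(0:3, n1, replace = TRUE)
      y <- if (i %% 2) rnorm(n2) else sample(0:3, n2, replace = TRUE)
      if (sd(c(x, y)) == 0) next
      p <- compare_groups(x, y, test = "mann_whitney_exact")$p_value
      expect_equal(p, oracle_mw_p(x, y))
      # symmetric under swapping the groups
      expect_equal(p, compare_groups(y, x, test = "mann_whitney_exact")$p_value)
      expect_gt(p, 0); expect_lte(p, 1)
      # agrees with the standard implementation when there are no ties
      if (!any(duplicated(c(x, y)))) {
        expect_equal(p, wilcox.test(x, y, exact = TRUE)$p.value)
      }
    }
  })
})

test_that("Welch comparison flags constant data instead of failing", {
  expect_warning(res <- compare_groups(c(1, 1, 1), c(1, 1, 1), test = "welch_t"),
                 "constant")
  expect_equal(res$p_value, 1)
  ok <- compare_groups(rnorm(5), rnorm(5) + 10, test = "welch_t")
  expect_lt(ok$p_value, 0.01)
})
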