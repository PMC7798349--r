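small_cfg <- function(...) {
  simulation_config(n_genes_per_species = 4, reads_mean = 8000, reads_sd = 500, ...)
}

test_that("a generated study has the full design cardinality and is seed-stable", {
  cfg <- small_cfg(seed = 5)
  st <- generate_study(cfg)
  expect_equal(nrow(st$metadata), 12)
  expect_equal(table(as.character(st$metadata$group))[["control"]], 6)
  expect_equal(sort(unique(st$metadata$sex)), c("F", "M"))
  expect_equal(ncol(st$taxa$values), 7)
  expect_length(st$transcripts, 7)
  expect_length(st$bile_acids, 3)
  expect_named(st$bile_acids, c("cecum", "liver", "serum"))

  st2 <- generate_study(cfg)
  expect_identical(st$taxa$values, st2$taxa$values)
  expect_identical(st$transcripts[[3]]$values, st2$transcripts[[3]]$values)
  expect_identical(st$bile_acids$cecum$values, st2$bile_acids$cecum$values)
  st3 <- generate_study(small_cfg(seed = 6))
  expect_false(identical(st$taxa$values, st3$taxa$values))

  comb <- combine_study(st)
  expect_equal(ncol(comb$values),
               7 * 4 + 3 * nrow(ba_registry()) + 7)
})

test_that("invalid planted effects are refused", {
  expect_error(
    generate_study(small_cfg(planted_de = tibble::tibble(
      gene = "nope", species = "Bilophila_wadsworthia", log2fc = 2
    ))),
    "planted gene not in genome"
  )
  expect_error(
    generate_study(small_cfg(planted_corr = tibble::tibble(
      gene = "x", species = "Bilophila_wadsworthia", analyte = "NOT_A_BA",
      compartment = "cecum", group = "berberine", target_rho = 0.9
    ))),
    "planted analyte not in panel"
  )
  expect_error(simulation_config(planted_corr = tibble::tibble(
    gene = "x", species = "Bilophila_wadsworthia", analyte = "DCA",
    compartment = "cecum", group = "berberine", target_rho = 1.0
  )), "target_rho")
})

test_that("simulated cecal totals recover the configured group means", {
  cfg <- simulation_config(n_genes_per_species = 1, seed = 1)
  totals <- purrr::map_dfr(1:60, function(i) {
    cfg$seed <- i
    st <- generate_study(cfg)
    total_bile_acids(st$bile_acids$cecum) |>
      dplyr::group_by(group) |>
      dplyr::summarise(m = mean(total), .groups = "drop")
  })
  ctl <- totals$m[totals$group == "control"]
  trt <- totals$m[totals$group == "berberine"]
  expect_lt(abs(mean(ctl) - 1.29), 3 * sd(ctl) / sqrt(length(ctl)) + 0.02)
  expect_lt(abs(mean(trt) - 4.57), 3 * sd(trt) / sqrt(length(trt)) + 0.07)
  # liver and serum means are group-invariant by design
  cfg$seed <- 99
  st <- generate_study(cfg)
  lt <- total_bile_acids(st$bile_acids$liver)
  expect_lt(
    abs(mean(lt$total[lt$group == "control"]) -
          mean(lt$total[lt$group == "berberine"])),
    3 * sd(lt$total)
  )
})

test_that("latent coupling is calibrated, signed, and group-specific", {
  # beta = 0 leaves the pair independent
  expect_equal(calibrate_coupling(0), 0)
  r0 <- bilenet:::empirical_coupled_rho(0, 0.1, 100, 0.4, 10000, seed = 2)
  expect_lt(abs(r0), 0.05)

  b <- calibrate_coupling(0.9, seed = 3)
  cfg <- small_cfg(
    planted_corr = tibble::tibble(
      gene = "Bwads_g001", species = "Bilophila_wadsworthia",
      analyte = "DCA", compartment = "cecum", group = "berberine",
      target_rho = 0.9, beta = b
    ),
    seed = 11
  )
  rho_hat <- empirical_rho(cfg, 1, n_large = 10000)
  expect_gte(rho_hat, 0.85)
  expect_lte(rho_hat, 0.95)

  # negative targets flip the sign of the realized correlation
  cfg_neg <- cfg
  cfg_neg$planted_corr$target_rho <- -0.9
  cfg_neg$planted_corr$beta <- -b
  expect_lt(empirical_rho(cfg_neg, 1, n_large = 10000), -0.85)

  # correlation appears only in the planted group
  rhos <- purrr::map_dfr(1:25, function(i) {
    cfg$seed <- 100 + i
    st <- generate_study(cfg)
    comb <- combine_study(st, include_taxa = FALSE)
    pair <- planted_pair_ids(st)
    trt <- filter_group(comb, "berberine")
    ctl <- filter_group(comb, "control")
    tibble::tibble(
      trt = spearman_rho(trt$values[, pair$feature_a], trt$values[, pair$feature_b]),
      ctl = spearman_rho(ctl$values[, pair$feature_a], ctl$values[, pair$feature_b])
    )
  })
  expect_gt(mean(rhos$trt), 0.6)   # strong in the planted group at n = 6
  expect_lt(abs(mean(rhos$ctl)), 0.25) # centered at zero in the other group
})
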