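#' Planted-network recovery experiment
#'
#' Repeatedly generates a synthetic study with planted group-specific
#' gene-analyte correlations, runs the per-group correlation networks and
#' the correlation-difference network, and scores how well the planted
#' pairs are recovered. Recall is the fraction of planted pairs present as
#' edges; precision is the fraction of all edges that are planted pairs.
#' For the per-group network, recovery is scored in the group the pairs
#' were planted in.
#'
#' @param config A [simulation_config()] whose `planted_corr` is non-empty.
#' @param n_sims Number of simulated studies (seeds `seed`, `seed+1`, ...).
#' @param rho_min,p_max Per-group network thresholds (defaults 0.7, 0.05).
#' @param alpha Difference-network threshold (default 0.01).
#' @param diff_method Difference test (default `"fisher_z"`).
#' @param cor_method Per-group p-value method (default `"auto"`: exact at
#'   group n <= 9).
#' @param include_taxa Include taxon features in the combined table.
#' @param seed Base seed.
#' @return Tibble with one row per simulation: recall/precision of the
#'   planted group's network (`group_recall`, `group_precision`, edge count
#'   `group_edges`) and of the difference network (`diff_recall`,
#'   `diff_precision`, `diff_edges`), plus `n_planted` and `n_features`.
#' @export
evaluate_network_recovery <- function(config, n_sims = 50,
                                      rho_min = 0.7, p_max = 0.05,
                                      alpha = 0.01,
                                      diff_method = "fisher_z",
                                      cor_method = "auto",
                                      include_taxa = FALSE,
                                      seed = 1) {
  stopifnot(inherits(config, "simulation_config"))
  if (nrow(config$planted_corr) == 0) abort("config has no planted correlations")
  groups_planted <- unique(config$planted_corr$group)
  if (length(groups_planted) != 1) {
    abort("recovery scoring expects all pairs planted in one group")
  }
  grp <- groups_planted

  purrr::map_dfr(seq_len(n_sims), function(i) {
    cfg <- config
    cfg$seed <- derive_seed(seed, paste0("sim", i))
    study <- generate_study(cfg)
    combined <- combine_study(study, include_taxa = include_taxa)
    planted <- planted_pair_ids(study)
    truth_keys <- pair_key(planted$feature_a, planted$feature_b)

    rec <- suppressMessages(
      all_pairs_correlation(combined, grp, method = cor_method)
    )
    net <- build_network(rec, rho_min = rho_min, p_max = p_max,
                         annotations = combined$features)
    net_keys <- pair_key(net$edges$feature_i, net$edges$feature_j)

    dc <- suppressMessages(suppressWarnings(
      differential_correlations(combined, method = diff_method)
    ))
    dnet <- difference_network(dc, alpha = alpha,
                               annotations = combined$features)
    dnet_keys <- pair_key(dnet$edges$feature_i, dnet$edges$feature_j)

    tibble(
      sim = i,
      n_planted = length(truth_keys),
      n_features = ncol(combined$values),
      group_edges = length(net_keys),
      group_recall = mean(truth_keys %in% net_keys),
      group_precision = if (length(net_keys) > 0) {
        mean(net_keys %in% truth_keys)
      } else NA_real_,
      diff_edges = length(dnet_keys),
      diff_recall = mean(truth_keys %in% dnet_keys),
      diff_precision = if (length(dnet_keys) > 0) {
        mean(dnet_keys %in% truth_keys)
      } else NA_real_
    )
  })
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "<>")

#' Default planted-recovery study design
#'
#' A convenience [simulation_config()] with `n_pairs` gene-analyte
#' correlations planted in the treatment group at `target_rho`, and enough
#' genes to give roughly `n_null` uninvolved features, used by the
#' recovery experiments.
#'
#' @param n_pairs Number of planted pairs (default 10).
#' @param target_rho Planted rank correlation (default 0.9).
#' @param n_null Approximate number of null features (default 200).
#' @param beta Optional pre-calibrated coupling (skips calibration).
#' @param seed Seed.
#' @return A `simulation_config`.
#' @export
recovery_config <- function(n_pairs = 10, target_rho = 0.9, n_null = 200,
                            beta = NULL, seed = 1) {
  taxa <- consortium_species()
  # genes spread over species; analytes from the cecal panel
  n_genes <- ceiling((n_null + n_pairs) / length(taxa)) + 2
  cfg <- simulation_config(n_genes_per_species = n_genes, seed = seed)
  species <- rep(taxa, length.out = n_pairs)
  analytes <- rep(ba_registry()$analyte_id, length.out = n_pairs)
  planted <- tibble(
    gene = vapply(seq_len(n_pairs), function(k) {
      simulated_gene_ids(cfg, species[k])[k %/% length(taxa) + 1]
    }, character(1)),
    species = species,
    analyte = analytes,
    compartment = "cecum",
    group = "berberine",
    target_rho = target_rho,
    beta = if (is.null(beta)) NA_real_ else beta
  )
  simulation_config(n_genes_per_species = n_genes, planted_corr = planted,
                    seed = seed)
}
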