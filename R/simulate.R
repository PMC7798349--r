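#' Configuration for the synthetic study generator
#'
#' Encodes the study design the generator emulates: two treatment groups
#' (control / berberine) of `n_per_group` gnotobiotic mice (balanced males
#' and females), a 7-member defined bacterial community sequenced to about
#' 53,000 +/- 3,600 16S reads per sample, per-species transcriptomes as
#' negative binomial counts, and bile acid panels for cecum, liver and
#' serum whose cecal totals average 1.29 umol/g in controls and
#' 4.57 umol/g under treatment (treatment scales the cecal analyte means by
#' that ratio; liver and serum means are group-invariant). Differential
#' expression is planted via `planted_de` (true log2 fold changes) and
#' group-specific gene-analyte rank correlations via `planted_corr`:
#' a per-sample latent Gaussian factor enters both the gene's NB log-mean
#' and the analyte's log-concentration, in the configured group only, with
#' coupling strength `beta` (calibrated numerically from `target_rho` when
#' not given).
#'
#' @param n_per_group Mice per group (default 6; 3 male, 3 female).
#' @param taxa Taxon names (default the 7 consortium members).
#' @param base_composition Relative abundances of `taxa` (summing to 1).
#' @param reads_mean,reads_sd 16S sequencing depth distribution.
#' @param n_genes_per_species Genes simulated per species (default 150).
#' @param nb_dispersion NB dispersion of transcript counts (default 0.1).
#' @param gene_mean_log,gene_mean_sdlog Log-normal parameters of baseline
#'   gene expression means.
#' @param planted_de Tibble (`gene`, `species`, `log2fc`) of planted
#'   differentially expressed genes (default none).
#' @param planted_corr Tibble (`gene`, `species`, `analyte`, `compartment`,
#'   `group`, `target_rho`, optionally `beta`) of planted group-specific
#'   gene-analyte correlations (default none).
#' @param ba_panel Analyte registry with `control_mean_*` columns (default
#'   [ba_registry()]).
#' @param cecal_total_control,cecal_total_treatment Expected cecal total
#'   bile acids, umol/g (defaults 1.29 and 4.57).
#' @param ba_sdlog_control,ba_sdlog_treatment Log-scale SD of cecal analyte
#'   concentrations per group (defaults 0.15, 0.40, matching the reported
#'   total variability); `ba_sdlog_other` applies to liver/serum.
#' @param taxa_sdlog Log-scale SD of per-sample taxon composition noise.
#' @param seed Integer seed; the same config and seed reproduce the study
#'   bit-identically.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_per_group = 6,
                              taxa = consortium_species(),
                              base_composition = c(0.30, 0.22, 0.15, 0.08, 0.10, 0.09, 0.06),
                              reads_mean = 53000, reads_sd = 3600,
                              n_genes_per_species = 150,
                              nb_dispersion = 0.1,
                              gene_mean_log = log(100), gene_mean_sdlog = 1,
                              planted_de = NULL,
                              planted_corr = NULL,
                              ba_panel = ba_registry(),
                              cecal_total_control = 1.29,
                              cecal_total_treatment = 4.57,
                              ba_sdlog_control = 0.15,
                              ba_sdlog_treatment = 0.40,
                              ba_sdlog_other = 0.30,
                              taxa_sdlog = 0.30,
                              seed = 1) {
  stopifnot(length(base_composition) == length(taxa),
            all(base_composition > 0),
            reads_mean > 0, n_genes_per_species > 0, nb_dispersion > 0,
            cecal_total_control > 0, cecal_total_treatment > 0)
  planted_de <- if (is.null(planted_de)) {
    tibble(gene = character(), species = character(), log2fc = numeric())
  } else as_tibble(planted_de)
  planted_corr <- if (is.null(planted_corr)) {
    tibble(gene = character(), species = character(), analyte = character(),
           compartment = character(), group = character(),
           target_rho = numeric(), beta = numeric())
  } else {
    pc <- as_tibble(planted_corr)
    if (!"beta" %in% names(pc)) pc$beta <- NA_real_
    if (any(abs(pc$target_rho) >= 1)) abort("|target_rho| must be < 1")
    pc
  }
  structure(
    list(
      n_per_group = n_per_group, taxa = taxa,
      base_composition = base_composition / sum(base_composition),
      reads_mean = reads_mean, reads_sd = reads_sd,
      n_genes_per_species = n_genes_per_species,
      nb_dispersion = nb_dispersion,
      gene_mean_log = gene_mean_log, gene_mean_sdlog = gene_mean_sdlog,
      planted_de = planted_de, planted_corr = planted_corr,
      ba_panel = as_tibble(ba_panel),
      cecal_total_control = cecal_total_control,
      cecal_total_treatment = cecal_total_treatment,
      ba_sdlog_control = ba_sdlog_control,
      ba_sdlog_treatment = ba_sdlog_treatment,
      ba_sdlog_other = ba_sdlog_other,
      taxa_sdlog = taxa_sdlog,
      seed = seed
    ),
    class = "simulation_config"
  )
}

#' Generate a complete synthetic study
#'
#' @param config A [simulation_config()].
#' @return A `synthetic_study` list: `metadata` tibble, `taxa` count
#'   `feature_table`, `transcripts` (named list of per-species count
#'   tables), `bile_acids` (list of cecum/liver/serum concentration
#'   tables), and `truth` (planted DE, planted correlations with calibrated
#'   beta, and the per-sample latent factors).
#' @export
generate_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  check_planted(cfg)

  n <- cfg$n_per_group
  metadata <- tibble(
    sample_id = c(sprintf("C%02d", seq_len(n)), sprintf("B%02d", seq_len(n))),
    group = rep(GROUP_LEVELS, each = n),
    sex = rep(rep(c("M", "F"), length.out = n), 2)
  )
  treated <- metadata$group == "berberine"

  # calibrate any coupling strengths not given (deterministic in the seed)
  pc <- cfg$planted_corr
  if (nrow(pc) > 0 && anyNA(pc$beta)) {
    for (k in which(is.na(pc$beta))) {
      pc$beta[k] <- calibrate_coupling(
        target_rho = pc$target_rho[k],
        nb_dispersion = cfg$nb_dispersion,
        gene_mean = exp(cfg$gene_mean_log),
        analyte_sdlog = analyte_sdlog_for(cfg, pc$compartment[k], pc$group[k]),
        seed = derive_seed(cfg$seed, paste0("calibrate", k))
      )
    }
  }

  withr::with_seed(cfg$seed, {
    ns <- nrow(metadata)

    # latent factors: one per planted correlation, one value per sample
    z <- matrix(rnorm(max(nrow(pc), 1) * ns), ncol = ns)
    rownames(z) <- if (nrow(pc) > 0) paste0("factor", seq_len(nrow(pc))) else "factor1"
    colnames(z) <- metadata$sample_id

    # --- taxa ---------------------------------------------------------
    depth <- pmax(1000L, as.integer(round(rnorm(ns, cfg$reads_mean, cfg$reads_sd))))
    taxa_counts <- matrix(0L, ns, length(cfg$taxa),
                          dimnames = list(metadata$sample_id, cfg$taxa))
    for (s in seq_len(ns)) {
      lp <- log(cfg$base_composition) + rnorm(length(cfg$taxa), 0, cfg$taxa_sdlog)
      pr <- exp(lp) / sum(exp(lp))
      taxa_counts[s, ] <- as.integer(rmultinom(1, depth[s], pr))
    }
    taxa_ft <- feature_table(
      taxa_counts, metadata,
      tibble(feature_id = cfg$taxa, feature_type = "taxon",
             compartment = "cecum", species = NA_character_),
      kind = "counts"
    )

    # --- transcripts per species -------------------------------------
    transcripts <- list()
    for (sp in cfg$taxa) {
      g_ids <- sprintf("%s_g%03d", abbreviate_species(sp), seq_len(cfg$n_genes_per_species))
      mu0 <- rlnorm(cfg$n_genes_per_species, cfg$gene_mean_log, cfg$gene_mean_sdlog)
      lfc <- numeric(cfg$n_genes_per_species)
      pd <- cfg$planted_de |> filter(.data$species == sp)
      if (nrow(pd) > 0) lfc[match(pd$gene, g_ids)] <- pd$log2fc
      logmu <- outer(log(mu0), rep(1, ns)) +
        outer(lfc * log(2), as.numeric(treated))
      pc_sp <- pc |> filter(.data$species == sp)
      if (nrow(pc_sp) > 0) {
        for (k in seq_len(nrow(pc_sp))) {
          gi <- match(pc_sp$gene[k], g_ids)
          krow <- match_planted_row(pc, pc_sp[k, ])
          in_grp <- metadata$group == pc_sp$group[k]
          # gene side always loads positively; the analyte side carries the
          # sign, so sign(beta) = sign(rho). The NB mean is mu * exp(b z)
          # (no lognormal mean correction: a shrinking mean would collapse
          # low-z samples onto tied zero counts and cap the attainable rho)
          b <- abs(pc_sp$beta[k])
          logmu[gi, in_grp] <- logmu[gi, in_grp] + b * z[krow, in_grp]
        }
      }
      counts <- matrix(
        rnbinom(length(logmu), mu = exp(logmu), size = 1 / cfg$nb_dispersion),
        nrow = nrow(logmu), dimnames = list(g_ids, metadata$sample_id)
      )
      transcripts[[sp]] <- feature_table(
        t(counts), metadata,
        tibble(feature_id = g_ids, feature_type = "transcript",
               compartment = "cecum", species = sp),
        kind = "counts"
      )
    }

    # --- bile acid panels --------------------------------------------
    bile_acids <- list()
    for (comp in c("cecum", "liver", "serum")) {
      means <- cfg$ba_panel[[paste0("control_mean_", comp)]]
      conc <- matrix(0, ns, nrow(cfg$ba_panel),
                     dimnames = list(metadata$sample_id, cfg$ba_panel$analyte_id))
      scale_trt <- if (comp == "cecum") cfg$cecal_total_treatment / cfg$cecal_total_control else 1
      for (s in seq_len(ns)) {
        m <- means * if (treated[s]) scale_trt else 1
        sdl <- analyte_sdlog_for(cfg, comp, metadata$group[s])
        conc[s, ] <- rlnorm(length(m), log(m) - sdl^2 / 2, sdl)
      }
      pc_c <- pc |> filter(.data$compartment == comp)
      if (nrow(pc_c) > 0) {
        for (k in seq_len(nrow(pc_c))) {
          ai <- match(pc_c$analyte[k], cfg$ba_panel$analyte_id)
          krow <- match_planted_row(pc, pc_c[k, ])
          in_grp <- metadata$group == pc_c$group[k]
          b <- pc_c$beta[k]
          conc[in_grp, ai] <- conc[in_grp, ai] * exp(b * z[krow, in_grp] - b^2 / 2)
        }
      }
      feats <- tibble(
        feature_id = cfg$ba_panel$analyte_id, feature_type = "bile_acid",
        compartment = comp, species = NA_character_,
        conjugation = cfg$ba_panel$conjugation,
        origin = cfg$ba_panel$origin,
        sulfated = cfg$ba_panel$sulfated
      )
      bile_acids[[comp]] <- feature_table(conc, metadata, feats,
                                          kind = "concentrations")
    }

    structure(
      list(
        metadata = metadata, taxa = taxa_ft, transcripts = transcripts,
        bile_acids = bile_acids,
        truth = list(planted_de = cfg$planted_de, planted_corr = pc,
                     latent = z),
        config = cfg
      ),
      class = "synthetic_study"
    )
  })
}

abbreviate_species <- function(sp) {
  parts <- strsplit(sp, "_")[[1]]
  paste0(substr(parts[1], 1, 1), substr(parts[length(parts)], 1, 4))
}

analyte_sdlog_for <- function(cfg, compartment, group) {
  if (compartment != "cecum") return(cfg$ba_sdlog_other)
  if (as.character(group) == "berberine") cfg$ba_sdlog_treatment else cfg$ba_sdlog_control
}

match_planted_row <- function(pc, row) {
  which(pc$gene == row$gene & pc$species == row$species &
          pc$analyte == row$analyte & pc$group == row$group)[1]
}

check_planted <- function(cfg) {
  pd <- cfg$planted_de
  if (nrow(pd) > 0) {
    bad_sp <- setdiff(pd$species, cfg$taxa)
    if (length(bad_sp) > 0) abort(paste("planted_de species not in taxa:",
                                        paste(bad_sp, collapse = ", ")))
    ids <- function(sp) sprintf("%s_g%03d", abbreviate_species(sp),
                                seq_len(cfg$n_genes_per_species))
    for (i in seq_len(nrow(pd))) {
      if (!pd$gene[i] %in% ids(pd$species[i])) {
        abort(paste("planted gene not in genome:", pd$gene[i]))
      }
    }
  }
  pc <- cfg$planted_corr
  if (nrow(pc) > 0) {
    bad_sp <- setdiff(pc$species, cfg$taxa)
    if (length(bad_sp) > 0) abort(paste("planted_corr species not in taxa:",
                                        paste(bad_sp, collapse = ", ")))
    bad_an <- setdiff(pc$analyte, cfg$ba_panel$analyte_id)
    if (length(bad_an) > 0) abort(paste("planted analyte not in panel:",
                                        paste(bad_an, collapse = ", ")))
    bad_grp <- setdiff(pc$group, GROUP_LEVELS)
    if (length(bad_grp) > 0) abort(paste("planted group must be control/berberine:",
                                         paste(bad_grp, collapse = ", ")))
    bad_comp <- setdiff(pc$compartment, c("cecum", "liver", "serum"))
    if (length(bad_comp) > 0) abort(paste("planted compartment invalid:",
                                          paste(bad_comp, collapse = ", ")))
  }
  invisible(cfg)
}

#' Gene ids of one simulated species
#'
#' @param config A [simulation_config()].
#' @param species One of `config$taxa`.
#' @return Character vector of gene ids the generator will use.
#' @export
simulated_gene_ids <- function(config, species) {
  stopifnot(species %in% config$taxa)
  sprintf("%s_g%03d", abbreviate_species(species),
          seq_len(config$n_genes_per_species))
}

#' Combine a synthetic study into the single feature table
#'
#' Column-binds all per-species transcript tables, the three bile acid
#' panels and the taxon counts into the combined table the correlation
#' networks run on.
#'
#' @param study A `synthetic_study`.
#' @param include_taxa Include the taxon counts as features (default TRUE).
#' @return A combined `feature_table`.
#' @export
combine_study <- function(study, include_taxa = TRUE) {
  stopifnot(inherits(study, "synthetic_study"))
  tables <- c(unname(study$transcripts), unname(study$bile_acids))
  if (include_taxa) tables <- c(tables, list(study$taxa))
  combine_features(tables)
}

#' Combined-table feature ids of the planted correlation pairs
#'
#' @param study A `synthetic_study`.
#' @return The study's planted correlations with `feature_a`/`feature_b`
#'   columns holding the prefixed ids used in [combine_study()] output.
#' @export
planted_pair_ids <- function(study) {
  stopifnot(inherits(study, "synthetic_study"))
  pc <- study$truth$planted_corr
  if (nrow(pc) == 0) {
    return(mutate(pc, feature_a = character(0), feature_b = character(0)))
  }
  pc |>
    mutate(
      feature_a = paste("cecum", .data$species, .data$gene, sep = "|"),
      feature_b = paste(.data$compartment, "bile_acid", .data$analyte, sep = "|")
    )
}

#' Calibrate the latent coupling strength for a target rank correlation
#'
#' Finds by bisection the coupling beta such that a gene (negative binomial
#' around mean `gene_mean` with dispersion `nb_dispersion`, log-mean offset
#' beta * z) and an analyte (log-normal with log-scale SD `analyte_sdlog`,
#' log offset beta * z) sharing a standard normal latent factor z have
#' Spearman correlation `target_rho` in a large sample.
#'
#' @param target_rho Target Spearman correlation, |rho| < 1.
#' @param nb_dispersion,gene_mean,analyte_sdlog Noise parameters of the two
#'   coupled features.
#' @param n_large Monte Carlo sample size (default 10000).
#' @param seed Seed for the calibration draws.
#' @param tol Bisection tolerance on rho (default 0.01).
#' @return The calibrated beta (signed like `target_rho`).
#' @export
calibrate_coupling <- function(target_rho, nb_dispersion = 0.1,
                               gene_mean = 100, analyte_sdlog = 0.4,
                               n_large = 10000, seed = 1, tol = 0.01) {
  if (abs(target_rho) >= 1) abort("|target_rho| must be < 1")
  if (target_rho == 0) return(0)
  rho_at <- function(b) {
    empirical_coupled_rho(b, nb_dispersion, gene_mean, analyte_sdlog,
                          n_large, seed)
  }
  lo <- 0.01; hi <- 8
  r_hi <- rho_at(hi)
  if (r_hi < abs(target_rho)) {
    abort(sprintf(
      "target rho %.2f unattainable under this noise model (max achievable ~ %.3f)",
      target_rho, r_hi
    ))
  }
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    r <- rho_at(mid)
    if (abs(r - abs(target_rho)) < tol) break
    if (r < abs(target_rho)) lo <- mid else hi <- mid
  }
  sign(target_rho) * mid
}

empirical_coupled_rho <- function(beta, nb_dispersion, gene_mean,
                                  analyte_sdlog, n_large, seed) {
  withr::with_seed(seed, {
    z <- rnorm(n_large)
    g <- rnbinom(n_large, mu = gene_mean * exp(abs(beta) * z),
                 size = 1 / nb_dispersion)
    a <- rlnorm(n_large, abs(beta) * z, analyte_sdlog)
    cor(g, a, method = "spearman")
  })
}

#' Large-sample rank correlation realized by a planted pair
#'
#' Simulates the coupling mechanism of one planted pair at a large n and
#' returns the empirical Spearman correlation (used to verify that the
#' calibrated beta reproduces the target rho).
#'
#' @param config A [simulation_config()].
#' @param pair One row of `config$planted_corr` (or an index into it).
#' @param n_large Sample size (default 10000).
#' @return Empirical Spearman rho.
#' @export
empirical_rho <- function(config, pair, n_large = 10000) {
  stopifnot(inherits(config, "simulation_config"))
  pc <- config$planted_corr
  if (is.numeric(pair)) pair <- pc[pair, ]
  krow <- match_planted_row(pc, pair)
  if (is.na(krow)) abort("pair is not among the planted correlations")
  beta <- pc$beta[krow]
  if (is.na(beta)) {
    beta <- calibrate_coupling(
      pc$target_rho[krow], config$nb_dispersion, exp(config$gene_mean_log),
      analyte_sdlog_for(config, pc$compartment[krow], pc$group[krow]),
      seed = derive_seed(config$seed, paste0("calibrate", krow))
    )
  }
  sign(beta) * empirical_coupled_rho(
    beta, config$nb_dispersion, exp(config$gene_mean_log),
    analyte_sdlog_for(config, pc$compartment[krow], pc$group[krow]),
    n_large, derive_seed(config$seed, "empirical")
  )
}
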