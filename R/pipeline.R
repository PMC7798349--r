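#' Pipeline configuration
#'
#' All thresholds default to the study's analysis settings: network filter
#' |rho| >= 0.7 at p <= 0.05, correlation-difference threshold p <= 0.01,
#' DE selection |log2FC| > 0.58 at p < 0.05, rarefaction to 23,900 reads,
#' ANOSIM with 999 permutations.
#'
#' @param rho_min,p_max Correlation network thresholds.
#' @param diff_alpha Difference-network threshold.
#' @param lfc_min,de_p DE selection thresholds.
#' @param rarefaction_depth Reads per sample after rarefaction.
#' @param anosim_perms ANOSIM permutations.
#' @param de_method `"perm_t"` or `"welch_t"`.
#' @param diff_method `"fisher_z"` or `"permutation"`.
#' @param cor_method `"auto"`, `"exact"` or `"t_approx"`.
#' @param shannon_base `"e"` or `"2"`.
#' @param include_taxa Include taxon counts as network features.
#' @param seed Integer seed for all randomized stages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(rho_min = 0.7, p_max = 0.05, diff_alpha = 0.01,
                            lfc_min = 0.58, de_p = 0.05,
                            rarefaction_depth = 23900, anosim_perms = 999,
                            de_method = "perm_t", diff_method = "fisher_z",
                            cor_method = "auto", shannon_base = "e",
                            include_taxa = TRUE, seed = 1) {
  stopifnot(rho_min >= 0, rho_min <= 1, p_max > 0, p_max <= 1,
            diff_alpha > 0, diff_alpha <= 1, lfc_min >= 0,
            de_p > 0, de_p <= 1, rarefaction_depth > 0, anosim_perms >= 1)
  structure(
    list(rho_min = rho_min, p_max = p_max, diff_alpha = diff_alpha,
         lfc_min = lfc_min, de_p = de_p,
         rarefaction_depth = rarefaction_depth, anosim_perms = anosim_perms,
         de_method = de_method, diff_method = diff_method,
         cor_method = cor_method, shannon_base = shannon_base,
         include_taxa = include_taxa, seed = seed),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes, in order: bile acid quantitation summaries, community
#' diversity statistics (rarefaction, Shannon + Mann-Whitney, Bray-Curtis,
#' NMDS, ANOSIM), per-species differential expression, per-group
#' correlation networks, and the correlation-difference network. Every
#' stage writes TSV artifacts under `out_dir` plus a JSON run manifest of
#' the parameters and seed; any stage failure aborts with the stage name
#' and leaves the manifest marked incomplete.
#'
#' @param study A `synthetic_study` from [generate_study()], or an
#'   equivalent list with `metadata`, `taxa`, `transcripts`, `bile_acids`.
#' @param config A [pipeline_config()].
#' @param out_dir Run directory (created if missing).
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(study, config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (missing(out_dir)) abort("out_dir is required")
  for (field in c("metadata", "taxa", "transcripts", "bile_acids")) {
    if (is.null(study[[field]])) abort(paste("study is missing", field,
                                             "(fail-fast before any computation)"))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- list(
    parameters = unclass(config),
    seed = config$seed,
    package = as.character(utils::packageVersion("bilenet")),
    complete = FALSE
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    inform(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(log_lines, paste0("FAILED at stage '", name, "': ",
                                     conditionMessage(e))), log_path)
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  results <- list()

  results$quantify <- stage("quantify", {
    say("stage quantify: bile acid totals and class summaries")
    out <- purrr::imap(study$bile_acids, function(panel, comp) {
      totals <- total_bile_acids(panel)
      cls <- purrr::map_dfr(
        c("conjugation", "origin", "sulfated"),
        function(by) ba_class_summary(panel, by) |> mutate(by = by)
      )
      cmp <- compare_groups(totals$total[totals$group == "control"],
                            totals$total[totals$group == "berberine"],
                            test = "welch_t") |>
        mutate(compartment = comp)
      readr::write_tsv(totals, file.path(out_dir, paste0("ba_totals_", comp, ".tsv")),
                       progress = FALSE)
      readr::write_tsv(cls, file.path(out_dir, paste0("ba_classes_", comp, ".tsv")),
                       progress = FALSE)
      list(totals = totals, classes = cls, comparison = cmp)
    })
    out
  })

  results$diversity <- stage("diversity", {
    say("stage diversity: rarefaction, Shannon, Bray-Curtis, NMDS, ANOSIM")
    rar <- withCallingHandlers(
      rarefy(study$taxa, depth = config$rarefaction_depth,
             seed = derive_seed(config$seed, "rarefy")),
      warning = function(w) { say("  ", conditionMessage(w)); invokeRestart("muffleWarning") }
    )
    sh <- shannon_diversity(rar, base = config$shannon_base)
    sh_test <- compare_groups(sh$shannon[sh$group == "control"],
                              sh$shannon[sh$group == "berberine"],
                              test = "mann_whitney_exact")
    bc <- bray_curtis_matrix(rar)
    ord <- nmds(bc, k = 2, seed = derive_seed(config$seed, "nmds"))
    an <- anosim(bc, n_perm = config$anosim_perms,
                 seed = derive_seed(config$seed, "anosim"))
    readr::write_tsv(sh, file.path(out_dir, "shannon.tsv"), progress = FALSE)
    readr::write_tsv(as_tibble(as.data.frame(unclass(bc)), rownames = "sample_id"),
                     file.path(out_dir, "bray_curtis.tsv"), progress = FALSE)
    readr::write_tsv(ord$points, file.path(out_dir, "nmds_coordinates.tsv"),
                     progress = FALSE)
    jsonlite::write_json(
      list(anosim = as.list(an), shannon_test = as.list(sh_test),
           nmds_stress = ord$stress),
      file.path(out_dir, "diversity_stats.json"), auto_unbox = TRUE, digits = NA
    )
    list(rarefied = rar, shannon = sh, shannon_test = sh_test,
         bray_curtis = bc, nmds = ord, anosim = an)
  })

  results$de <- stage("differential_expression", {
    say("stage differential_expression: per-species TMM + permutation t")
    de <- purrr::imap_dfr(study$transcripts, function(tab, sp) {
      run_de(tab, method = config$de_method,
             seed = derive_seed(config$seed, paste0("de", sp)))
    })
    selected <- filter_de(de, lfc_min = config$lfc_min, p_max = config$de_p)
    readr::write_tsv(de, file.path(out_dir, "de_results.tsv"), progress = FALSE)
    readr::write_tsv(selected, file.path(out_dir, "de_selected.tsv"),
                     progress = FALSE)
    list(results = de, selected = selected)
  })

  results$networks <- stage("correlation_networks", {
    say("stage correlation_networks: all-pairs Spearman per group")
    combined <- if (inherits(study, "synthetic_study")) {
      combine_study(study, include_taxa = config$include_taxa)
    } else {
      tables <- c(unname(study$transcripts), unname(study$bile_acids))
      if (config$include_taxa) tables <- c(tables, list(study$taxa))
      combine_features(tables)
    }
    nets <- purrr::map(setNames(GROUP_LEVELS, GROUP_LEVELS), function(grp) {
      rec <- withCallingHandlers(
        all_pairs_correlation(combined, grp, method = config$cor_method),
        message = function(m) { say("  ", conditionMessage(m)); invokeRestart("muffleMessage") }
      )
      net <- build_network(rec, rho_min = config$rho_min, p_max = config$p_max,
                           annotations = combined$features)
      readr::write_tsv(rec, file.path(out_dir, paste0("correlations_", grp, ".tsv")),
                       progress = FALSE)
      write_edge_list(net, file.path(out_dir, paste0("network_", grp, "_edges.tsv")))
      write_graphml(net, file.path(out_dir, paste0("network_", grp, ".graphml")))
      write_sif(net, file.path(out_dir, paste0("network_", grp, ".sif")))
      list(records = rec, network = net)
    })
    list(combined = combined, groups = nets)
  })

  results$diffnet <- stage("difference_network", {
    say("stage difference_network: correlation differences between groups")
    dc <- withCallingHandlers(
      differential_correlations(results$networks$combined,
                                method = config$diff_method,
                                seed = derive_seed(config$seed, "diffnet")),
      message = function(m) { say("  ", conditionMessage(m)); invokeRestart("muffleMessage") },
      warning = function(w) { say("  ", conditionMessage(w)); invokeRestart("muffleWarning") }
    )
    dnet <- difference_network(dc, alpha = config$diff_alpha,
                               annotations = results$networks$combined$features)
    readr::write_tsv(dc, file.path(out_dir, "correlation_differences.tsv"),
                     progress = FALSE)
    write_edge_list(dnet, file.path(out_dir, "difference_network_edges.tsv"))
    write_sif(dnet, file.path(out_dir, "difference_network.sif"))
    list(diffcors = dc, network = dnet)
  })

  topo <- bind_rows(
    network_topology(results$networks$groups$control$network) |>
      mutate(network = "control"),
    network_topology(results$networks$groups$berberine$network) |>
      mutate(network = "berberine"),
    network_topology(results$diffnet$network) |> mutate(network = "difference")
  )
  readr::write_tsv(topo, file.path(out_dir, "network_topology.tsv"),
                   progress = FALSE)
  results$topology <- topo

  manifest$complete <- TRUE
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, log_path)
  invisible(results)
}

#' Summarize a completed pipeline run
#'
#' Reads the artifacts of a [run_pipeline()] run directory back into a
#' summary: per-group and difference network topology, changed-pair
#' counts, DE counts per species, and the diversity statistics.
#'
#' @param run_dir A directory written by [run_pipeline()].
#' @return A `pipeline_report` list of tibbles.
#' @export
pipeline_report <- function(run_dir) {
  manifest_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(manifest_path)) abort("no manifest.json: not a run directory")
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (!isTRUE(manifest$complete)) abort("run is marked incomplete")

  topo <- readr::read_tsv(file.path(run_dir, "network_topology.tsv"),
                          show_col_types = FALSE)
  de <- readr::read_tsv(file.path(run_dir, "de_results.tsv"),
                        show_col_types = FALSE)
  de_sel <- readr::read_tsv(file.path(run_dir, "de_selected.tsv"),
                            show_col_types = FALSE)
  diffs <- readr::read_tsv(file.path(run_dir, "correlation_differences.tsv"),
                           show_col_types = FALSE)
  dstats <- jsonlite::read_json(file.path(run_dir, "diversity_stats.json"),
                                simplifyVector = TRUE)
  de_counts <- de_sel |>
    group_by(.data$species) |>
    summarise(n_de = n(), .groups = "drop")
  structure(
    list(
      topology = topo,
      de_counts = de_counts,
      n_de_total = nrow(de_sel),
      n_genes_tested = nrow(de),
      n_changed_pairs = sum(diffs$p <= manifest$parameters$diff_alpha,
                            na.rm = TRUE),
      diversity = tibble(
        anosim_R = dstats$anosim$R, anosim_p = dstats$anosim$p_value,
        shannon_p = dstats$shannon_test$p_value,
        nmds_stress = dstats$nmds_stress
      ),
      parameters = manifest$parameters
    ),
    class = "pipeline_report"
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  genes tested: %d; selected DE genes: %d\n",
              x$n_genes_tested, x$n_de_total))
  cat(sprintf("  changed correlation pairs (p <= %.3g): %d\n",
              x$parameters$diff_alpha, x$n_changed_pairs))
  cat(sprintf("  ANOSIM R = %.3f (p = %.3f); Shannon Mann-Whitney p = %.3f\n",
              x$diversity$anosim_R, x$diversity$anosim_p, x$diversity$shannon_p))
  print(x$topology)
  invisible(x)
}

#' Write a synthetic study to a directory of TSV files
#'
#' Writes the same dialects the readers consume: metadata TSV, taxon count
#' TSV, per-species transcript TSVs, per-compartment bile acid TSVs, and a
#' JSON truth ledger of the planted effects.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_sample_metadata(study$metadata, file.path(dir, "metadata.tsv"))
  write_feature_table(study$taxa, file.path(dir, "taxa.tsv"))
  for (sp in names(study$transcripts)) {
    write_feature_table(study$transcripts[[sp]],
                        file.path(dir, paste0("transcripts_", sp, ".tsv")))
  }
  for (comp in names(study$bile_acids)) {
    write_feature_table(study$bile_acids[[comp]],
                        file.path(dir, paste0("bile_acids_", comp, ".tsv")))
  }
  jsonlite::write_json(
    list(planted_de = study$truth$planted_de,
         planted_corr = study$truth$planted_corr),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a study directory written by [write_study()]
#'
#' @param dir Directory containing `metadata.tsv`, `taxa.tsv`,
#'   `transcripts_*.tsv` and `bile_acids_*.tsv`.
#' @return A list with `metadata`, `taxa`, `transcripts`, `bile_acids`
#'   (feature tables), usable by [run_pipeline()].
#' @export
read_study <- function(dir) {
  md_path <- file.path(dir, "metadata.tsv")
  if (!file.exists(md_path)) abort("metadata.tsv not found (fail-fast)")
  metadata <- read_sample_metadata(md_path)
  taxa <- read_feature_table(file.path(dir, "taxa.tsv"), metadata,
                             kind = "counts", default_type = "taxon")
  tr_files <- list.files(dir, pattern = "^transcripts_.*\\.tsv$", full.names = TRUE)
  transcripts <- setNames(
    lapply(tr_files, function(f) {
      sp <- sub("^transcripts_(.*)\\.tsv$", "\\1", basename(f))
      read_feature_table(f, metadata, kind = "counts",
                         default_type = "transcript",
                         default_compartment = "cecum", default_species = sp)
    }),
    sub("^transcripts_(.*)\\.tsv$", "\\1", basename(tr_files))
  )
  ba_files <- list.files(dir, pattern = "^bile_acids_.*\\.tsv$", full.names = TRUE)
  registry <- ba_registry()
  bile_acids <- setNames(
    lapply(ba_files, function(f) {
      comp <- sub("^bile_acids_(.*)\\.tsv$", "\\1", basename(f))
      read_feature_table(
        f, metadata, kind = "concentrations",
        annotations = registry |>
          mutate(feature_id = .data$analyte_id, feature_type = "bile_acid",
                 compartment = comp, species = NA_character_),
        default_type = "bile_acid", default_compartment = comp
      )
    }),
    sub("^bile_acids_(.*)\\.tsv$", "\\1", basename(ba_files))
  )
  list(metadata = metadata, taxa = taxa, transcripts = transcripts,
       bile_acids = bile_acids)
}
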