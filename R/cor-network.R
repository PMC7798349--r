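#' Build a correlation network from filtered records
#'
#' Keeps an edge when |rho| >= `rho_min` and p <= `p_max` (thresholds
#' |r| >= 0.7 and P <= 0.05 by default; the magnitude filter keeps negative
#' correlations, whose sign is stored on the edge). Optionally BH-adjusts
#' the p-values before filtering.
#'
#' @param records Correlation records tibble (`feature_i`, `feature_j`,
#'   `rho`, `n`, `p`, ...).
#' @param rho_min Minimum |rho| (default 0.7).
#' @param p_max Maximum p (default 0.05).
#' @param annotations Optional feature-annotation tibble (`feature_id`,
#'   `feature_type`, `compartment`, `species`) attached to nodes.
#' @param keep_isolated If `TRUE` and `annotations` given, all annotated
#'   features become nodes; otherwise only features with >= 1 edge.
#' @param adjust_p BH-adjust p-values before filtering (default `FALSE`:
#'   the network filter is on raw per-pair p).
#' @return A `cor_network`: list with `nodes` and `edges` tibbles and the
#'   `thresholds` used.
#' @export
build_network <- function(records, rho_min = 0.7, p_max = 0.05,
                          annotations = NULL, keep_isolated = FALSE,
                          adjust_p = FALSE) {
  records <- as_tibble(records)
  needed <- c("feature_i", "feature_j", "rho", "p")
  stopifnot(all(needed %in% names(records)))
  if (any(records$feature_i == records$feature_j)) abort("self-edge in records")
  if (adjust_p && nrow(records) > 0) records$p <- bh_fdr(records$p)
  edges <- records |>
    filter(abs(.data$rho) >= rho_min, .data$p <= p_max) |>
    mutate(sign = ifelse(.data$rho >= 0, "positive", "negative"))

  node_ids <- sort(unique(c(edges$feature_i, edges$feature_j)))
  if (keep_isolated && !is.null(annotations)) node_ids <- sort(unique(annotations$feature_id))
  nodes <- tibble(feature_id = node_ids)
  if (!is.null(annotations)) {
    nodes <- nodes |> left_join(as_tibble(annotations) |> distinct(.data$feature_id, .keep_all = TRUE),
                                by = "feature_id")
  }
  structure(
    list(nodes = nodes, edges = edges,
         thresholds = c(rho_min = rho_min, p_max = p_max)),
    class = "cor_network"
  )
}

#' @export
print.cor_network <- function(x, ...) {
  cat(sprintf(
    "<cor_network> %d nodes, %d edges (|rho| >= %.2g, p <= %.2g)\n",
    nrow(x$nodes), nrow(x$edges), x$thresholds["rho_min"], x$thresholds["p_max"]
  ))
  invisible(x)
}

as_igraph <- function(g) {
  stopifnot(inherits(g, "cor_network"))
  if (nrow(g$nodes) == 0) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  edges <- g$edges
  igraph::graph_from_data_frame(
    d = edges[, c("feature_i", "feature_j",
                  setdiff(names(edges), c("feature_i", "feature_j")))],
    directed = FALSE,
    vertices = as.data.frame(g$nodes)
  )
}

#' Topology summary of a network
#'
#' @param g A `cor_network`.
#' @return One-row tibble: `n_nodes`, `n_edges`, `n_components`, `density`,
#'   `n_negative_edges`, `n_cross_type_edges` (edges joining different
#'   feature types, e.g. transcript-bile acid), `mean_degree`.
#' @export
network_topology <- function(g) {
  stopifnot(inherits(g, "cor_network"))
  n <- nrow(g$nodes); m <- nrow(g$edges)
  if (n == 0) {
    return(tibble(n_nodes = 0L, n_edges = 0L, n_components = 0L, density = 0,
                  n_negative_edges = 0L, n_cross_type_edges = 0L, mean_degree = 0))
  }
  ig <- as_igraph(g)
  cross <- 0L
  if ("feature_type" %in% names(g$nodes)) {
    type <- setNames(g$nodes$feature_type, g$nodes$feature_id)
    cross <- sum(type[g$edges$feature_i] != type[g$edges$feature_j], na.rm = TRUE)
  }
  tibble(
    n_nodes = n,
    n_edges = m,
    n_components = igraph::count_components(ig),
    density = if (n > 1) m / choose(n, 2) else 0,
    n_negative_edges = if ("rho" %in% names(g$edges)) sum(g$edges$rho < 0) else 0L,
    n_cross_type_edges = as.integer(cross),
    mean_degree = if (n > 0) 2 * m / n else 0
  )
}

#' Per-node degrees
#'
#' @param g A `cor_network`.
#' @return Tibble `feature_id`, `degree` (degrees sum to twice the edge
#'   count).
#' @export
network_degrees <- function(g) {
  stopifnot(inherits(g, "cor_network"))
  counts <- table(factor(c(g$edges$feature_i, g$edges$feature_j),
                         levels = g$nodes$feature_id))
  tibble(feature_id = names(counts), degree = as.integer(counts))
}

#' Neighborhood sub-network around a focal feature
#'
#' Induced subgraph on the nodes within graph distance `radius` of the
#' focal feature (e.g. the sub-network around cecal DCA).
#'
#' @param g A `cor_network`.
#' @param focal Feature id, must be a node of `g`.
#' @param radius Graph radius (default 1; 0 returns the focal node alone).
#' @return A `cor_network`.
#' @export
subnetwork <- function(g, focal, radius = 1) {
  stopifnot(inherits(g, "cor_network"))
  if (!focal %in% g$nodes$feature_id) abort(paste("focal feature not in network:", focal))
  ig <- as_igraph(g)
  keep <- names(igraph::ego(ig, order = radius, nodes = focal)[[1]])
  edges <- g$edges |> filter(.data$feature_i %in% keep, .data$feature_j %in% keep)
  nodes <- g$nodes |> filter(.data$feature_id %in% keep)
  structure(list(nodes = nodes, edges = edges, thresholds = g$thresholds),
            class = "cor_network")
}

#' Export a network edge list as TSV
#' @param g A `cor_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "cor_network"))
  readr::write_tsv(g$edges, path, progress = FALSE)
  invisible(path)
}

#' Export a network as GraphML (Cytoscape-importable)
#' @inheritParams write_edge_list
#' @export
write_graphml <- function(g, path) {
  ig <- as_igraph(g)
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' Export a network as SIF (Cytoscape simple interaction format)
#'
#' Interaction type encodes the correlation sign
#' (`pos_correlation`/`neg_correlation`).
#'
#' @inheritParams write_edge_list
#' @export
write_sif <- function(g, path) {
  stopifnot(inherits(g, "cor_network"))
  rel <- if (nrow(g$edges) > 0 && "rho" %in% names(g$edges)) {
    ifelse(g$edges$rho >= 0, "pos_correlation", "neg_correlation")
  } else character(0)
  lines <- if (nrow(g$edges) > 0) {
    paste(g$edges$feature_i, rel, g$edges$feature_j, sep = "\t")
  } else character(0)
  iso <- setdiff(g$nodes$feature_id, c(g$edges$feature_i, g$edges$feature_j))
  writeLines(c(lines, iso), path)
  invisible(path)
}
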