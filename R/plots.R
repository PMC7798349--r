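#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_segment geom_col
#'   geom_tile labs theme_minimal scale_linewidth_continuous facet_wrap
#'   scale_fill_gradient2
NULL

#' @export
ggplot2::autoplot

#' Plot a correlation network
#'
#' Fruchterman-Reingold layout with nodes colored by feature type and edge
#' width scaled by |rho| (solid sign encoded by color).
#'
#' @param object A `cor_network`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cor_network <- function(object, seed = 1, ...) {
  g <- object
  if (nrow(g$nodes) == 0) {
    return(ggplot() + labs(title = "empty network") + theme_minimal())
  }
  ig <- as_igraph(g)
  xy <- withr::with_seed(seed, igraph::layout_with_fr(ig))
  lay <- tibble(feature_id = igraph::V(ig)$name, x = xy[, 1], y = xy[, 2]) |>
    left_join(g$nodes, by = "feature_id")
  if (!"feature_type" %in% names(lay)) lay$feature_type <- "feature"
  weight_col <- if ("rho" %in% names(g$edges)) "rho" else "delta"
  ed <- g$edges |>
    left_join(lay |> select("feature_id", xi = "x", yi = "y"),
              by = c(feature_i = "feature_id")) |>
    left_join(lay |> select("feature_id", xj = "x", yj = "y"),
              by = c(feature_j = "feature_id")) |>
    mutate(weight = abs(.data[[weight_col]]),
           sign = ifelse(.data[[weight_col]] >= 0, "positive", "negative"))
  p <- ggplot()
  if (nrow(ed) > 0) {
    p <- p + geom_segment(
      data = ed,
      aes(x = .data$xi, y = .data$yi, xend = .data$xj, yend = .data$yj,
          linewidth = .data$weight, color = .data$sign),
      alpha = 0.6
    ) + scale_linewidth_continuous(range = c(0.2, 1.2))
  }
  p +
    geom_point(data = lay, aes(x = .data$x, y = .data$y,
                               shape = .data$feature_type), size = 2) +
    labs(x = NULL, y = NULL, color = "sign", shape = "type",
         linewidth = "|correlation|") +
    theme_minimal()
}

#' Plot an NMDS ordination
#'
#' @param object An `nmds` object.
#' @param ... Unused.
#' @return A ggplot of the first two ordination axes, colored by group
#'   when known.
#' @export
autoplot.nmds <- function(object, ...) {
  pts <- object$points
  p <- ggplot(pts, aes(x = .data$NMDS1, y = .data$NMDS2))
  p <- if ("group" %in% names(pts) && !all(is.na(pts$group))) {
    p + geom_point(aes(color = .data$group), size = 2)
  } else {
    p + geom_point(size = 2)
  }
  p + labs(caption = sprintf("stress-1 = %.3f", object$stress)) +
    theme_minimal()
}

#' Stacked bile acid composition per sample
#'
#' @param panel A bile-acid `feature_table`.
#' @param by Fill grouping: `"analyte"` or a class column
#'   (`"conjugation"`, `"origin"`, `"sulfated"`).
#' @return A ggplot of per-sample stacked concentrations.
#' @export
plot_ba_composition <- function(panel, by = "analyte") {
  stopifnot(inherits(panel, "feature_table"))
  long <- as_tibble(panel)
  fill <- if (by == "analyte") "feature_id" else by
  if (!fill %in% names(long)) abort(paste("unknown class column:", by))
  ggplot(long, aes(x = .data$sample_id, y = .data$value,
                   fill = as.character(.data[[fill]]))) +
    geom_col() +
    facet_wrap(~group, scales = "free_x") +
    labs(x = NULL, y = "concentration", fill = by) +
    theme_minimal()
}

#' Heat map of selected differentially expressed genes
#'
#' @param norm Gene x sample matrix of normalized log2 expression.
#' @param selected Tibble of selected genes (from [filter_de()]).
#' @param groups Group labels aligned with the matrix columns.
#' @return A ggplot tile map of row-standardized expression.
#' @export
plot_de_heatmap <- function(norm, selected, groups) {
  genes <- intersect(selected$gene_id, rownames(norm))
  if (length(genes) == 0) abort("no selected genes present in the matrix")
  m <- norm[genes, , drop = FALSE]
  m <- (m - rowMeans(m)) / apply(m, 1, sd)
  long <- tibble(
    gene_id = rep(rownames(m), times = ncol(m)),
    sample_id = rep(colnames(m), each = nrow(m)),
    group = rep(as.character(groups), each = nrow(m)),
    z = as.vector(m)
  )
  ggplot(long, aes(x = .data$sample_id, y = .data$gene_id, fill = .data$z)) +
    geom_tile() +
    scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    facet_wrap(~group, scales = "free_x") +
    labs(x = NULL, y = NULL, fill = "z(log2 expr)") +
    theme_minimal()
}
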