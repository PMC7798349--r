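#' TMM normalization factors and log2-CPM expression
#'
#' Between-library scaling by the trimmed mean of M-values: for each
#' library vs. a reference, per-gene log2 ratios (M) and average log2
#' abundances (A) are computed over genes expressed in both; the most
#' extreme 30% of M and 5% of A are trimmed; the factor is 2^(weighted mean
#' of M) with inverse-asymptotic-variance weights. The reference library is
#' the one whose upper-quartile/library-size ratio is closest to the mean
#' such ratio. Factors are re-centered to geometric mean 1. Expression is
#' returned as log2 counts-per-million with a prior count (default 0.5) on
#' the effective (factor-scaled) library sizes.
#'
#' @param counts Gene x sample integer matrix (or a count `feature_table`).
#' @param prior Prior count added before the log (default 0.5).
#' @param m_trim,a_trim Two-sided trim fractions for M and A (defaults 0.3
#'   and 0.05).
#' @return List: `log2cpm` (gene x sample matrix), `factors` tibble
#'   (`sample_id`, `lib_size`, `tmm_factor`), `reference` sample id.
#' @export
normalize_counts <- function(counts, prior = 0.5, m_trim = 0.3, a_trim = 0.05) {
  counts <- counts_matrix(counts)
  lib <- colSums(counts)
  if (any(lib == 0)) {
    abort(paste("all-zero sample:", colnames(counts)[lib == 0][1]))
  }
  uq <- apply(counts, 2, function(y) quantile(y[y > 0], 0.75)) / lib
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref], m_trim, a_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  eff <- lib * f
  log2cpm <- log2(t((t(counts) + prior) / (eff + 2 * prior)) * 1e6)
  list(
    log2cpm = log2cpm,
    factors = tibble(sample_id = colnames(counts), lib_size = unname(lib),
                     tmm_factor = unname(f)),
    reference = colnames(counts)[ref]
  )
}

tmm_pair <- function(obs, ref, n_obs, n_ref, m_trim, a_trim) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) return(1)
  o <- obs[keep]; r <- ref[keep]
  m <- log2((o / n_obs) / (r / n_ref))
  a <- 0.5 * log2((o / n_obs) * (r / n_ref))
  w <- (n_obs - o) / (n_obs * o) + (n_ref - r) / (n_ref * r)
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * m_trim) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * a_trim) + 1; hi_a <- n + 1 - lo_a
  keep2 <- rank(m, ties.method = "first") >= lo_m & rank(m, ties.method = "first") <= hi_m &
    rank(a, ties.method = "first") >= lo_a & rank(a, ties.method = "first") <= hi_a
  if (!any(keep2)) return(1)
  2^(sum(m[keep2] / w[keep2]) / sum(1 / w[keep2]))
}

counts_matrix <- function(counts) {
  if (inherits(counts, "feature_table")) {
    m <- t(counts$values) # gene x sample
  } else {
    m <- as.matrix(counts)
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  m
}

#' Per-gene log2 fold change between groups
#'
#' Difference of group means of normalized log2 expression, treatment minus
#' control.
#'
#' @param norm Gene x sample matrix of log2 expression.
#' @param groups Group labels (control/berberine) aligned with columns.
#' @return Named numeric vector of log2 fold changes.
#' @export
log2_fold_change <- function(norm, groups) {
  groups <- check_group_labels(groups)
  if (any(tabulate(groups, 2) == 0)) abort("both groups must be non-empty")
  rowMeans(norm[, groups == "berberine", drop = FALSE]) -
    rowMeans(norm[, groups == "control", drop = FALSE])
}

#' Per-gene two-group test on normalized expression
#'
#' `perm_t`: the group labels are permuted and the Welch t statistic
#' recomputed for every relabeling; when all `choose(n, n1)` splits number
#' at most `n_perm` they are fully enumerated (924 at n = 6+6) and
#' p = #\{|t*| >= |t|\}/N, else `n_perm` random splits are drawn and
#' p = (#\{|t*| >= |t|\} + 1)/(n_perm + 1). `welch_t` is the parametric
#' Welch test. Genes constant across all samples get p = 1 and are flagged.
#'
#' @param norm Gene x sample matrix of normalized log2 expression.
#' @param groups Group labels aligned with columns.
#' @param method `"perm_t"` (default) or `"welch_t"`.
#' @param n_perm Permutation budget (default 2000).
#' @param seed Seed for sampled permutations.
#' @return Tibble: `gene_id`, `statistic`, `p_value`, `constant`.
#' @export
de_test <- function(norm, groups, method = c("perm_t", "welch_t"),
                    n_perm = 2000, seed = 1) {
  method <- match.arg(method)
  groups <- check_group_labels(groups)
  n1 <- sum(groups == "control"); n2 <- sum(groups == "berberine")
  if (method == "perm_t" && (n1 < 3 || n2 < 3)) {
    abort("perm_t needs at least 3 samples per group")
  }
  genes <- rownames(norm)
  constant <- apply(norm, 1, function(v) max(v) - min(v) < 1e-12)

  t_obs <- welch_t_rows(norm, groups == "control")

  if (method == "welch_t") {
    df <- welch_df_rows(norm, groups == "control")
    p <- 2 * pt(-abs(t_obs), df)
  } else {
    n <- ncol(norm)
    n_splits <- choose(n, n1)
    if (n_splits <= n_perm) {
      sel <- subset_indicators(n, n1)
      exceed <- integer(nrow(norm))
      for (i in seq_len(nrow(sel))) {
        t_perm <- welch_t_rows(norm, sel[i, ])
        exceed <- exceed + (abs(t_perm) >= abs(t_obs) - 1e-12)
      }
      p <- exceed / nrow(sel)
    } else {
      exceed <- integer(nrow(norm))
      withr::with_seed(seed, {
        for (i in seq_len(n_perm)) {
          in1 <- logical(n); in1[sample.int(n, n1)] <- TRUE
          t_perm <- welch_t_rows(norm, in1)
          exceed <- exceed + (abs(t_perm) >= abs(t_obs) - 1e-12)
        }
      })
      p <- (exceed + 1) / (n_perm + 1)
    }
  }
  p[constant] <- 1
  tibble(gene_id = genes, statistic = unname(t_obs), p_value = unname(pmin(p, 1)),
         constant = unname(constant))
}

# row-wise Welch t for a logical split (TRUE = group 1); constant rows -> 0
welch_t_rows <- function(m, in1) {
  x <- m[, in1, drop = FALSE]; y <- m[, !in1, drop = FALSE]
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (my - mx) / sqrt(se2)
  t[se2 == 0] <- 0
  t
}

welch_df_rows <- function(m, in1) {
  x <- m[, in1, drop = FALSE]; y <- m[, !in1, drop = FALSE]
  nx <- ncol(x); ny <- ncol(y)
  vx <- rowSums((x - rowMeans(x))^2) / (nx - 1)
  vy <- rowSums((y - rowMeans(y))^2) / (ny - 1)
  num <- (vx / nx + vy / ny)^2
  den <- (vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1)
  df <- num / den
  df[den == 0] <- nx + ny - 2
  df
}

#' Benjamini-Hochberg false discovery rates
#'
#' @param p Vector of p-values in (0, 1].
#' @return Vector of BH-adjusted q-values.
#' @export
bh_fdr <- function(p) {
  if (any(p <= 0 | p > 1)) abort("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Per-species differential expression
#'
#' Normalizes one species' count table (each organism's transcriptome is
#' its own composition, so species are normalized independently), computes
#' treatment-vs-control log2 fold changes and permutation-t p-values, and
#' attaches BH FDRs.
#'
#' @param counts A count `feature_table` of one species' genes, or a
#'   gene x sample matrix.
#' @param groups Group labels (taken from the table's metadata when
#'   `counts` is a `feature_table`).
#' @param species Species label carried into the result.
#' @inheritParams de_test
#' @return Tibble: `gene_id`, `species`, `log2fc`, `p`, `fdr`, `mean_expr`.
#' @export
run_de <- function(counts, groups = NULL, species = NA_character_,
                   method = c("perm_t", "welch_t"), n_perm = 2000, seed = 1) {
  method <- match.arg(method)
  if (inherits(counts, "feature_table") && is.null(groups)) {
    groups <- counts$samples$group
    if (is.na(species) && !all(is.na(counts$features$species))) {
      species <- counts$features$species[1]
    }
  }
  m <- counts_matrix(counts)
  norm <- normalize_counts(m)
  lfc <- log2_fold_change(norm$log2cpm, groups)
  tst <- de_test(norm$log2cpm, groups, method = method, n_perm = n_perm, seed = seed)
  tibble(
    gene_id = tst$gene_id,
    species = species,
    log2fc = unname(lfc),
    p = tst$p_value,
    fdr = bh_fdr(tst$p_value),
    mean_expr = unname(rowMeans(norm$log2cpm))
  )
}

#' Select differentially expressed genes
#'
#' Keeps genes with |log2FC| > `lfc_min` and p < `p_max` (the heat-map
#' filter log2FC > (-)0.58, P < 0.05).
#'
#' @param results Tibble from [run_de()] (needs `log2fc` and `p`).
#' @param lfc_min Absolute log2FC threshold (default 0.58).
#' @param p_max Raw p-value threshold (default 0.05).
#' @return The selected rows.
#' @export
filter_de <- function(results, lfc_min = 0.58, p_max = 0.05) {
  stopifnot(all(c("log2fc", "p") %in% names(results)))
  results |> filter(abs(.data$log2fc) > lfc_min, .data$p < p_max)
}
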