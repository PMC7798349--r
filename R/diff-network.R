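#' Fisher z-transform of a correlation
#'
#' atanh(rho); inputs with |rho| >= 1 (which occur at n = 6 with ties) are
#' clamped to 1 - 1e-6 in magnitude with a warning, since z diverges there.
#'
#' @param rho Correlation(s) in \[-1, 1\].
#' @return z value(s).
#' @export
fisher_z <- function(rho) {
  if (any(abs(rho) > 1 + 1e-12, na.rm = TRUE)) abort("|rho| > 1")
  clamped <- abs(rho) > 1 - 1e-6
  if (any(clamped, na.rm = TRUE)) {
    warn(paste(sum(clamped, na.rm = TRUE),
               "correlation(s) at |rho| ~ 1 clamped to 1 - 1e-6 before atanh"))
    rho <- sign(rho) * pmin(abs(rho), 1 - 1e-6)
  }
  atanh(rho)
}

#' Fisher z test for the difference of two independent correlations
#'
#' stat = (z1 - z2)/sqrt(1/(n1-3) + 1/(n2-3)); two-sided normal p. An
#' approximation at the study's n = 6; the permutation test
#' ([diff_test_permutation()]) is exact there.
#'
#' @param rho1,rho2 Correlations in the two groups.
#' @param n1,n2 Group sample sizes (>= 4).
#' @return Tibble: `stat`, `p_value`.
#' @export
diff_test_fisher <- function(rho1, n1, rho2, n2) {
  if (any(c(n1, n2) <= 3)) abort("Fisher z difference test needs n >= 4 per group")
  z1 <- fisher_z(rho1); z2 <- fisher_z(rho2)
  se <- sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  stat <- (z1 - z2) / se
  tibble(stat = stat, p_value = pmin(1, 2 * pnorm(-abs(stat))))
}

# Spearman rho of (x, y) within each subset (rows of `sel`, logical) of the
# pooled samples, computed tie-aware via midranks-within-subset, fully
# vectorized over subsets. Subsets where either feature is constant get
# rho = 0 (flagged via attribute).
spearman_within_subsets <- function(x, y, sel) {
  k <- rowSums(sel)[1]
  rx <- 1 + sel %*% pairwise_dominance(x)
  ry <- 1 + sel %*% pairwise_dominance(y)
  sxy <- rowSums(sel * rx * ry)
  sx2 <- rowSums(sel * rx^2)
  sy2 <- rowSums(sel * ry^2)
  s1 <- k * (k + 1) / 2
  vx <- k * sx2 - s1^2
  vy <- k * sy2 - s1^2
  num <- k * sxy - s1^2
  den <- sqrt(pmax(vx, 0) * pmax(vy, 0))
  rho <- ifelse(den > 1e-12, num / den, 0)
  attr(rho, "degenerate") <- den <= 1e-12
  rho
}

# A[j, i] = (x_j < x_i) + 0.5 (x_j == x_i), diagonal 0: rank of i within a
# subset s containing i is 1 + sum_{j in s} A[j, i]
pairwise_dominance <- function(x) {
  a <- outer(x, x, "<") + 0.5 * outer(x, x, "==")
  diag(a) <- 0
  a
}

#' Permutation test for a correlation difference between two groups
#'
#' The null keeps each sample's (x, y) pair intact and permutes which
#' samples belong to which group, recomputing |rho_2 - rho_1| for every
#' relabeling. All `choose(n1+n2, n1)` splits are enumerated when they
#' number at most `n_perm` (924 at n = 6+6, giving p = #\{|d*| >= |d|\}/N);
#' otherwise `n_perm` random splits are drawn and
#' p = (#\{|d*| >= |d|\} + 1)/(n_perm + 1). Splits in which a feature is
#' constant within a group contribute rho = 0 for that group.
#'
#' @param x1,y1 Paired feature values in group 1 (control).
#' @param x2,y2 Paired feature values in group 2 (treatment).
#' @param n_perm Permutation budget (default 2000).
#' @param seed Seed for sampled permutations.
#' @return One-row tibble: `rho1`, `rho2`, `delta`, `p_value`, `n_perm`,
#'   `method`.
#' @export
diff_test_permutation <- function(x1, y1, x2, y2, n_perm = 2000, seed = 1) {
  n1 <- length(x1); n2 <- length(x2)
  stopifnot(length(y1) == n1, length(y2) == n2)
  if (n1 < 4 || n2 < 4) abort("permutation difference test needs n >= 4 per group")
  x <- c(x1, x2); y <- c(y1, y2)
  n <- n1 + n2
  obs_in1 <- c(rep(TRUE, n1), rep(FALSE, n2))

  enumerate <- choose(n, n1) <= n_perm
  sel <- if (enumerate) {
    subset_indicators(n, n1)
  } else {
    withr::with_seed(seed, {
      m <- matrix(FALSE, n_perm, n)
      for (i in seq_len(n_perm)) m[i, sample.int(n, n1)] <- TRUE
      m
    })
  }
  mode(sel) <- "numeric"

  rho1_all <- spearman_within_subsets(x, y, sel)
  rho2_all <- spearman_within_subsets(x, y, 1 - sel)
  d_all <- abs(rho2_all - rho1_all)

  r1 <- spearman_rho(x1, y1); r2 <- spearman_rho(x2, y2)
  r1 <- if (is.na(r1)) 0 else r1
  r2 <- if (is.na(r2)) 0 else r2
  d_obs <- abs(r2 - r1)

  if (enumerate) {
    p <- mean(d_all >= d_obs - 1e-12)
    method <- "permutation_exact"
  } else {
    p <- (sum(d_all >= d_obs - 1e-12) + 1) / (nrow(sel) + 1)
    method <- "permutation_sampled"
  }
  tibble(rho1 = r1, rho2 = r2, delta = r2 - r1, p_value = p,
         n_perm = nrow(sel), method = method)
}

#' Correlation differences for all feature pairs
#'
#' For every feature pair testable in both groups (non-constant in each),
#' computes the control and treatment Spearman correlations and a p-value
#' for their difference, by the Fisher z test (default; pairs with a
#' correlation at |rho| ~ 1, where z diverges, are routed to the
#' permutation test automatically) or the group-label permutation test.
#'
#' @param x A combined `feature_table` containing both groups.
#' @param method `"fisher_z"` or `"permutation"`.
#' @param pairs Optional tibble (`feature_i`, `feature_j`) restricting the
#'   pairs tested (e.g. the union of per-group filtered edges).
#' @param n_perm,seed Passed to the permutation machinery.
#' @return Tibble: `feature_i`, `feature_j`, `rho_control`,
#'   `rho_treatment`, `delta`, `stat`, `p`, `method`; skipped (constant)
#'   features in `attr(, "skipped_features")`.
#' @export
differential_correlations <- function(x, method = c("fisher_z", "permutation"),
                                      pairs = NULL, n_perm = 2000, seed = 1) {
  stopifnot(inherits(x, "feature_table"))
  method <- match.arg(method)
  ctl <- filter_group(x, "control")
  trt <- filter_group(x, "berberine")
  n1 <- nrow(ctl$values); n2 <- nrow(trt$values)
  if (n1 < 4 || n2 < 4) abort("each group needs >= 4 samples")

  const1 <- apply(ctl$values, 2, function(v) max(v) - min(v) < 1e-12)
  const2 <- apply(trt$values, 2, function(v) max(v) - min(v) < 1e-12)
  skip <- colnames(x$values)[const1 | const2]
  if (length(skip) > 0) {
    inform(paste("skipping features constant in a group:", paste(skip, collapse = ", ")))
  }
  keep <- !(const1 | const2)
  ids <- colnames(x$values)[keep]
  if (length(ids) < 2) abort("fewer than 2 testable features")

  rank1 <- apply(ctl$values[, keep, drop = FALSE], 2, rank)
  rank2 <- apply(trt$values[, keep, drop = FALSE], 2, rank)
  rho1_m <- cor(rank1)
  rho2_m <- cor(rank2)

  if (is.null(pairs)) {
    idx <- which(upper.tri(rho1_m), arr.ind = TRUE)
  } else {
    pi_ <- match(pairs$feature_i, ids)
    pj <- match(pairs$feature_j, ids)
    ok <- !is.na(pi_) & !is.na(pj)
    idx <- cbind(row = pmin(pi_[ok], pj[ok]), col = pmax(pi_[ok], pj[ok]))
    idx <- idx[!duplicated(idx), , drop = FALSE]
  }
  rho1 <- rho1_m[idx]
  rho2 <- rho2_m[idx]

  out <- tibble(
    feature_i = pmin(ids[idx[, 1]], ids[idx[, 2]]),
    feature_j = pmax(ids[idx[, 1]], ids[idx[, 2]]),
    rho_control = rho1,
    rho_treatment = rho2,
    delta = rho2 - rho1,
    stat = NA_real_,
    p = NA_real_,
    method = method
  )

  vc <- ctl$values[, keep, drop = FALSE]
  vt <- trt$values[, keep, drop = FALSE]

  if (method == "fisher_z") {
    extreme <- abs(rho1) > 1 - 1e-6 | abs(rho2) > 1 - 1e-6
    if (any(!extreme)) {
      ft <- diff_test_fisher(rho1[!extreme], n1, rho2[!extreme], n2)
      out$stat[!extreme] <- ft$stat
      out$p[!extreme] <- ft$p_value
    }
    if (any(extreme)) {
      out$method[extreme] <- "permutation"
      for (r in which(extreme)) {
        i <- idx[r, 1]; j <- idx[r, 2]
        pt_ <- diff_test_permutation(vc[, i], vc[, j], vt[, i], vt[, j],
                                     n_perm = n_perm, seed = seed)
        out$p[r] <- pt_$p_value
      }
    }
  } else {
    n <- n1 + n2
    enumerate <- choose(n, n1) <= n_perm
    sel <- if (enumerate) subset_indicators(n, n1) else NULL
    x_all <- rbind(vc, vt)
    if (!is.null(sel)) {
      mode(sel) <- "numeric"
      comp <- 1 - sel
      dom <- lapply(seq_along(ids), function(i) pairwise_dominance(x_all[, i]))
      rk1 <- lapply(dom, function(a) 1 + sel %*% a)
      rk2 <- lapply(dom, function(a) 1 + comp %*% a)
      s1a <- n1 * (n1 + 1) / 2
      s1b <- n2 * (n2 + 1) / 2
      d_obs <- abs(rho2 - rho1)
      for (r in seq_len(nrow(idx))) {
        i <- idx[r, 1]; j <- idx[r, 2]
        ra <- subset_rho(rk1[[i]], rk1[[j]], sel, n1, s1a)
        rb <- subset_rho(rk2[[i]], rk2[[j]], comp, n2, s1b)
        out$p[r] <- mean(abs(rb - ra) >= d_obs[r] - 1e-12)
      }
      out$method <- "permutation_exact"
    } else {
      for (r in seq_len(nrow(idx))) {
        i <- idx[r, 1]; j <- idx[r, 2]
        pt_ <- diff_test_permutation(vc[, i], vc[, j], vt[, i], vt[, j],
                                     n_perm = n_perm, seed = seed)
        out$p[r] <- pt_$p_value
      }
      out$method <- "permutation_sampled"
    }
  }
  attr(out, "skipped_features") <- skip
  out
}

# rho within subsets from precomputed within-subset ranks
subset_rho <- function(rx, ry, sel, k, s1) {
  sxy <- rowSums(sel * rx * ry)
  sx2 <- rowSums(sel * rx^2)
  sy2 <- rowSums(sel * ry^2)
  den <- sqrt(pmax(k * sx2 - s1^2, 0) * pmax(k * sy2 - s1^2, 0))
  ifelse(den > 1e-12, (k * sxy - s1^2) / den, 0)
}

#' Correlation differences from two record sets
#'
#' Fisher z difference test applied to already-computed per-group
#' correlation records over the same feature universe (no raw data
#' needed).
#'
#' @param records_control,records_treatment Correlation record tibbles from
#'   [all_pairs_correlation()] for the two groups.
#' @return Diffcor tibble as in [differential_correlations()].
#' @export
diff_correlation_records <- function(records_control, records_treatment) {
  key <- function(r) paste(r$feature_i, r$feature_j, sep = "||")
  kc <- key(records_control); kt <- key(records_treatment)
  if (!setequal(kc, kt)) {
    d <- union(setdiff(kc, kt), setdiff(kt, kc))
    abort(paste0("record sets cover different feature pairs; difference: ",
                 paste(head(d, 10), collapse = ", "),
                 if (length(d) > 10) " ..." else ""))
  }
  merged <- dplyr::inner_join(
    records_control |> select("feature_i", "feature_j", rho_control = "rho",
                              n_control = "n"),
    records_treatment |> select("feature_i", "feature_j", rho_treatment = "rho",
                                n_treatment = "n"),
    by = c("feature_i", "feature_j")
  )
  ft <- diff_test_fisher(merged$rho_control, merged$n_control[1],
                         merged$rho_treatment, merged$n_treatment[1])
  merged |>
    mutate(delta = .data$rho_treatment - .data$rho_control,
           stat = ft$stat, p = ft$p_value, method = "fisher_z") |>
    select("feature_i", "feature_j", "rho_control", "rho_treatment",
           "delta", "stat", "p", "method")
}

#' Build the correlation-difference network
#'
#' Edges are the feature pairs whose correlation changed significantly
#' between treatments (difference-test p <= `alpha`, default 0.01); edge
#' attributes carry both group correlations, the change `delta`, and the
#' p-value.
#'
#' @param diffcors Tibble from [differential_correlations()] or
#'   [diff_correlation_records()].
#' @param alpha Significance threshold on the difference test (default
#'   0.01).
#' @param annotations Optional feature annotations for the nodes.
#' @return A `cor_network` whose edges are the changed pairs.
#' @export
difference_network <- function(diffcors, alpha = 0.01, annotations = NULL) {
  stopifnot(all(c("feature_i", "feature_j", "delta", "p") %in% names(diffcors)))
  edges <- diffcors |> filter(.data$p <= alpha)
  node_ids <- sort(unique(c(edges$feature_i, edges$feature_j)))
  nodes <- tibble(feature_id = node_ids)
  if (!is.null(annotations)) {
    nodes <- nodes |> left_join(as_tibble(annotations) |>
                                  distinct(.data$feature_id, .keep_all = TRUE),
                                by = "feature_id")
  }
  structure(
    list(nodes = nodes, edges = edges, thresholds = c(rho_min = NA, p_max = alpha)),
    class = "cor_network"
  )
}
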