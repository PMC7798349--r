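#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of whether between-group dissimilarities
#' exceed within-group dissimilarities. All pairwise distances are ranked
#' jointly (midranks for ties) and
#' R = (mean between-group rank - mean within-group rank) / (n(n-1)/4),
#' so R is 1 when every between-group distance exceeds every within-group
#' distance and near 0 under exchangeability. The p-value is one-sided
#' (large R): with `exact = TRUE` (default when the number of distinct
#' two-group label assignments is at most `n_perm`) every distinct
#' assignment is enumerated and p = #\{R* >= R\}/N; otherwise `n_perm`
#' random label permutations are drawn and p = (#\{R* >= R\} + 1)/(n_perm + 1).
#'
#' @param d A `distance_matrix` or symmetric matrix.
#' @param groups Group labels aligned with the rows of `d` (default: taken
#'   from the metadata attached to `d`). At least 2 groups, each of size
#'   >= 2.
#' @param n_perm Number of random permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @param exact Force (or forbid) full enumeration; `NULL` decides
#'   automatically (only available for 2 groups).
#' @return One-row tibble: `R`, `p_value`, `n_perm`, `method`.
#' @export
anosim <- function(d, groups = NULL, n_perm = 999, seed = 1, exact = NULL) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (is.null(groups)) {
    samples <- attr(d, "samples")
    if (is.null(samples)) abort("groups not given and d carries no sample metadata")
    groups <- samples$group
  }
  groups <- as.factor(groups)
  if (length(groups) != n) abort("groups length does not match distance matrix")
  sizes <- table(groups)
  if (length(sizes) < 2) abort("need at least 2 groups")
  if (any(sizes < 2)) {
    abort(paste("every group needs >= 2 samples; too small:",
                paste(names(sizes)[sizes < 2], collapse = ", ")))
  }

  low <- lower.tri(dm)
  rk <- matrix(0, n, n)
  rk[low] <- rank(dm[low])
  rk <- rk + t(rk)

  r_stat <- function(g) {
    same <- outer(g, g, "==")
    within <- rk[low & same]
    between <- rk[low & !same]
    (mean(between) - mean(within)) / (n * (n - 1) / 4)
  }
  r_obs <- r_stat(groups)

  two_groups <- length(sizes) == 2
  n_assign <- if (two_groups) choose(n, sizes[1]) else Inf
  if (is.null(exact)) exact <- two_groups && n_assign <= n_perm
  if (exact && !two_groups) abort("exact enumeration implemented for 2 groups only")

  if (exact) {
    lv <- levels(groups)
    sel <- subset_indicators(n, as.integer(sizes[1]))
    r_all <- apply(sel, 1, function(in1) {
      r_stat(factor(ifelse(in1, lv[1], lv[2]), levels = lv))
    })
    p <- mean(r_all >= r_obs - 1e-12)
    method <- "exact_enumeration"
    n_used <- nrow(sel)
  } else {
    r_perm <- withr::with_seed(seed, {
      vapply(seq_len(n_perm), function(i) r_stat(sample(groups)), numeric(1))
    })
    p <- (sum(r_perm >= r_obs - 1e-12) + 1) / (n_perm + 1)
    method <- "permutation"
    n_used <- n_perm
  }
  tibble(R = r_obs, p_value = p, n_perm = n_used, method = method)
}
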