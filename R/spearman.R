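#' Spearman rank correlation
#'
#' Pearson correlation of midranks (tie-aware); without ties this equals
#' the classical 1 - 6*sum(d^2)/(n(n^2-1)).
#'
#' @param x,y Numeric vectors, length >= 3.
#' @return rho in \[-1, 1\], or `NA` if either vector is constant.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  rx <- rank(x); ry <- rank(y)
  sx <- sd(rx); sy <- sd(ry)
  if (sx == 0 || sy == 0) return(NA_real_)
  sum((rx - mean(rx)) * (ry - mean(ry))) / ((length(x) - 1) * sx * sy)
}

#' Two-sided p-value for a Spearman correlation
#'
#' `exact` (n <= 9): the null distribution is built by enumerating all n!
#' permutations of the observed y midranks against the x midranks (ties are
#' preserved: the permutation null is over the observed tied vectors
#' themselves), p = #\{|rho*| >= |rho|\}/n!. This p is never 0; its floor is
#' 1/n! (2/n! for untied data, where a correlation and its reversal tie).
#' `t_approx`: t = rho*sqrt((n-2)/(1-rho^2)) on n-2 df.
#'
#' @param x,y Numeric vectors.
#' @param method `"exact"` (default, requires n <= 9) or `"t_approx"`.
#' @return Two-sided p in (0, 1].
#' @export
spearman_pvalue <- function(x, y, method = c("exact", "t_approx")) {
  method <- match.arg(method)
  rho <- spearman_rho(x, y)
  if (is.na(rho)) abort("constant vector: Spearman correlation undefined")
  n <- length(x)
  if (method == "t_approx") return(spearman_t_pvalue(rho, n))
  if (n > 9) abort("exact enumeration limited to n <= 9; use method = 't_approx'")
  null_abs <- spearman_null_abs(rank(x), rank(y))
  exceed <- length(null_abs) - findInterval(abs(rho) - 1e-12, null_abs)
  exceed / length(null_abs)
}

spearman_t_pvalue <- function(rho, n) {
  r2 <- min(rho^2, 1 - 1e-12)
  t <- abs(rho) * sqrt((n - 2) / (1 - r2))
  min(1, 2 * pt(-t, n - 2))
}

# sorted |rho*| over all permutations of ry against rx; cached by the tie
# pattern of the two midrank vectors (the null depends only on those)
spearman_null_abs <- function(rx, ry, cache = .spearman_null_cache) {
  n <- length(rx)
  kx <- paste(sort(rx), collapse = ",")
  ky <- paste(sort(ry), collapse = ",")
  key <- paste(n, min(kx, ky), max(kx, ky), sep = "|")
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  pm <- permutation_matrix(n)
  # rho for every permutation: linear in the permuted ranks
  rxc <- rx - mean(rx)
  denom <- (n - 1) * sd(rx) * sd(ry)
  perm_vals <- matrix(ry[pm], nrow(pm), n)
  s <- as.vector(perm_vals %*% rxc)
  null_abs <- sort(abs((s - sum(rxc) * mean(ry)) / denom))
  cache[[key]] <- null_abs
  null_abs
}

.spearman_null_cache <- new.env(parent = emptyenv())

#' All-pairs Spearman correlations within one treatment group
#'
#' Computes rho and p for every unordered feature pair of the combined
#' table, using only the given group's samples. Constant features are
#' skipped (their correlations are undefined) and reported via the
#' `skipped_features` attribute.
#'
#' @param x A combined `feature_table`.
#' @param group `"control"` or `"berberine"`.
#' @param method p-value method: `"auto"` (exact when group n <= 9, else
#'   t approximation), `"exact"`, `"t_approx"`.
#' @return Tibble of correlation records: `feature_i`, `feature_j`
#'   (canonical `i < j` order), `rho`, `n`, `p`, `group`; the skipped
#'   constant features in `attr(, "skipped_features")`.
#' @export
all_pairs_correlation <- function(x, group, method = c("auto", "exact", "t_approx")) {
  stopifnot(inherits(x, "feature_table"))
  method <- match.arg(method)
  sub <- filter_group(x, group)
  n <- nrow(sub$values)
  if (n < 4) abort("group must have at least 4 samples")
  if (method == "auto") method <- if (n <= 9) "exact" else "t_approx"

  v <- sub$values
  const <- apply(v, 2, function(col) max(col) - min(col) < 1e-12)
  skipped <- colnames(v)[const]
  if (length(skipped) > 0) {
    inform(paste("skipping constant features:", paste(skipped, collapse = ", ")))
  }
  v <- v[, !const, drop = FALSE]
  f <- ncol(v)
  if (f < 2) abort("fewer than 2 non-constant features")

  ranks <- apply(v, 2, rank)
  rho_m <- cor(ranks)
  pair <- which(upper.tri(rho_m), arr.ind = TRUE)
  rho <- rho_m[pair]

  if (method == "t_approx") {
    p <- vapply(rho, spearman_t_pvalue, numeric(1), n = n)
  } else {
    keys <- apply(ranks, 2, function(r) paste(sort(r), collapse = ","))
    p <- numeric(nrow(pair))
    pair_key <- paste(pmin(keys[pair[, 1]], keys[pair[, 2]]),
                      pmax(keys[pair[, 1]], keys[pair[, 2]]), sep = "||")
    for (k in unique(pair_key)) {
      idx <- which(pair_key == k)
      one <- idx[1]
      null_abs <- spearman_null_abs(ranks[, pair[one, 1]], ranks[, pair[one, 2]])
      p[idx] <- (length(null_abs) -
                   findInterval(abs(rho[idx]) - 1e-12, null_abs)) / length(null_abs)
    }
  }

  ids <- colnames(v)
  out <- tibble(
    feature_i = pmin(ids[pair[, 1]], ids[pair[, 2]]),
    feature_j = pmax(ids[pair[, 1]], ids[pair[, 2]]),
    rho = rho,
    n = n,
    p = p,
    group = group
  ) |> arrange(.data$feature_i, .data$feature_j)
  attr(out, "skipped_features") <- skipped
  out
}
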