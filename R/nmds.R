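#' Non-metric multidimensional scaling
#'
#' Embeds samples in k dimensions by minimizing Kruskal's stress-1,
#' sqrt(sum (d - dhat)^2 / sum d^2), where d are configuration distances
#' and dhat is the isotonic (monotone) regression of d on the rank order of
#' the input dissimilarities. Each iteration alternates an isotonic fit
#' (tied dissimilarities are ordered by current configuration distance, the
#' "primary" tie treatment) with a gradient step on the configuration whose
#' step size is halved until stress does not increase, so the stress trace
#' is non-increasing by construction. The best of `n_starts` restarts (a
#' classical-scaling start plus random starts) is returned.
#'
#' @param d A `distance_matrix` (or symmetric matrix with dimnames).
#' @param k Embedding dimension (default 2).
#' @param seed Integer seed for the random restarts.
#' @param n_starts Number of starts (default 20; the first is classical
#'   scaling).
#' @param max_iter Maximum iterations per start (default 300).
#' @param tol Stop when the stress decrease falls below this (default 1e-6).
#' @return An `nmds` object: `points` tibble (`sample_id`, `group` if known,
#'   `NMDS1..k`), `stress`, `iterations`, `converged`, `stress_trace`.
#' @export
nmds <- function(d, k = 2, seed = 1, n_starts = 20, max_iter = 300, tol = 1e-6) {
  dm <- as.matrix(d)
  if (any(!is.finite(dm))) abort("non-finite distances")
  n <- nrow(dm)
  if (n < k + 1) abort("need at least k + 1 samples")
  low <- dm[lower.tri(dm)]
  ord0 <- order(low)

  best <- NULL
  withr::with_seed(seed, {
    for (s in seq_len(n_starts)) {
      x0 <- if (s == 1) {
        cm <- cmdscale(dm, k = k)
        if (ncol(cm) < k) cbind(cm, matrix(rnorm(n * (k - ncol(cm)), sd = 1e-3), n))
        else cm
      } else {
        matrix(rnorm(n * k), n, k)
      }
      fit <- nmds_one_start(x0, low, max_iter, tol)
      if (is.null(best) || fit$stress < best$stress) best <- fit
    }
  })

  pts <- best$conf
  # canonical orientation: principal axes, centered
  pts <- scale(pts, scale = FALSE)
  pts <- pts %*% svd(pts)$v
  colnames(pts) <- paste0("NMDS", seq_len(k))
  samples <- attr(d, "samples")
  points <- tibble(sample_id = rownames(dm) %||% as.character(seq_len(n)))
  if (!is.null(samples)) points$group <- samples$group[match(points$sample_id, samples$sample_id)]
  points <- bind_cols(points, as_tibble(pts))

  structure(
    list(points = points, stress = best$stress, iterations = best$iterations,
         converged = best$converged, stress_trace = best$trace, k = k),
    class = "nmds"
  )
}

# stress-1 for a configuration given fixed disparities
stress1 <- function(dv, dhat) sqrt(sum((dv - dhat)^2) / sum(dv^2))

# monotone fit of configuration distances on dissimilarity order;
# ties in the dissimilarities are ordered by current distance (primary)
fit_disparities <- function(dv, low) {
  ord <- order(low, dv)
  dhat <- numeric(length(dv))
  dhat[ord] <- isoreg(dv[ord])$yf
  dhat
}

nmds_one_start <- function(x, low, max_iter, tol) {
  n <- nrow(x)
  pair <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  conf_dist <- function(x) {
    dx <- as.matrix(dist(x))
    dx[lower.tri(dx)]
  }
  dv <- conf_dist(x)
  dv[dv == 0] <- 1e-12
  dhat <- fit_disparities(dv, low)
  s <- stress1(dv, dhat)
  trace <- s
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    g <- stress_gradient(x, dv, dhat, pair)
    gn <- sqrt(sum(g^2))
    if (gn < 1e-14) { converged <- TRUE; break }
    step <- 0.1 * sqrt(sum(x^2)) / gn
    improved <- FALSE
    for (h in 1:20) {
      xn <- x - step * g
      dvn <- conf_dist(xn)
      dvn[dvn == 0] <- 1e-12
      dhatn <- fit_disparities(dvn, low)
      sn <- stress1(dvn, dhatn)
      if (sn <= s) { improved <- TRUE; break }
      step <- step / 2
    }
    if (!improved) { converged <- TRUE; break }
    x <- xn; dv <- dvn; dhat <- dhatn
    trace <- c(trace, sn)
    if (s - sn < tol) { s <- sn; converged <- TRUE; break }
    s <- sn
  }
  list(conf = x, stress = s, iterations = iter, converged = converged, trace = trace)
}

# gradient of stress-1 in the configuration, disparities held fixed
stress_gradient <- function(x, dv, dhat, pair) {
  sstar <- sum((dv - dhat)^2)
  tstar <- sum(dv^2)
  s <- sqrt(sstar / tstar)
  if (s == 0) return(matrix(0, nrow(x), ncol(x)))
  # d stress / d d_ij
  dd <- s * ((dv - dhat) / sstar - dv / tstar)
  g <- matrix(0, nrow(x), ncol(x))
  for (a in seq_len(ncol(x))) {
    diffs <- x[pair[, 1], a] - x[pair[, 2], a]
    contrib <- dd * diffs / dv
    g[, a] <- tabulate_sum(pair[, 1], contrib, nrow(x)) -
      tabulate_sum(pair[, 2], contrib, nrow(x))
  }
  g
}

tabulate_sum <- function(idx, w, n) {
  res <- numeric(n)
  agg <- rowsum(w, idx)
  res[as.integer(rownames(agg))] <- agg[, 1]
  res
}

#' @export
print.nmds <- function(x, ...) {
  cat(sprintf(
    "<nmds> k = %d, stress-1 = %.4f (%d iterations%s)\n",
    x$k, x$stress, x$iterations, if (x$converged) ", converged" else ""
  ))
  print(head(x$points))
  invisible(x)
}
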