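#' Rarefy a taxon count table
#'
#' Subsamples every sample's reads to a fixed depth without replacement,
#' equalizing sequencing effort before diversity statistics (the study
#' rarefied to 23,900 reads). Samples with fewer reads than `depth` are
#' dropped with a warning naming them.
#'
#' @param x A `feature_table` of counts (taxa x samples on disk; samples x
#'   taxa in memory).
#' @param depth Target reads per sample (default 23900).
#' @param seed Integer seed; the same seed reproduces the same subsample.
#' @return A rarefied `feature_table`; every remaining sample's counts sum
#'   exactly to `depth`.
#' @export
rarefy <- function(x, depth = 23900, seed = 1) {
  stopifnot(inherits(x, "feature_table"), x$kind == "counts")
  totals <- rowSums(x$values)
  low <- totals < depth
  if (all(low)) abort("no sample reaches the rarefaction depth")
  if (any(low)) {
    warn(paste(
      "dropping samples below depth", depth, ":",
      paste(rownames(x$values)[low], collapse = ", ")
    ))
  }
  vals <- x$values[!low, , drop = FALSE]
  out <- withr::with_seed(seed, {
    t(apply(vals, 1, rarefy_vector, depth = depth))
  })
  dimnames(out) <- dimnames(vals)
  feature_table(out, x$samples[!low, , drop = FALSE], x$features, kind = "counts")
}

# draw `depth` reads without replacement from one sample's counts
rarefy_vector <- function(counts, depth) {
  total <- sum(counts)
  if (total == depth) return(counts)
  picked <- sample.int(total, depth)
  bounds <- cumsum(counts)
  tabulate(findInterval(picked, c(0, bounds), left.open = TRUE), nbins = length(counts))
}

#' Shannon diversity of one count vector
#'
#' H = -sum p_i log p_i over taxa with positive counts.
#'
#' @param counts Non-negative numeric vector with at least one positive
#'   entry.
#' @param base Logarithm base: `"e"` (default) or `"2"`.
#' @return Shannon index H.
#' @export
shannon <- function(counts, base = c("e", "2")) {
  base <- match.arg(base)
  if (any(counts < 0)) abort("negative counts")
  total <- sum(counts)
  if (total == 0) abort("all-zero count vector")
  p <- counts[counts > 0] / total
  h <- -sum(p * log(p))
  if (base == "2") h <- h / log(2)
  h
}

#' Per-sample Shannon diversity of a table
#'
#' @param x A count `feature_table`.
#' @inheritParams shannon
#' @return Tibble with `sample_id`, `group`, `shannon`.
#' @export
shannon_diversity <- function(x, base = c("e", "2")) {
  stopifnot(inherits(x, "feature_table"))
  base <- match.arg(base)
  tibble(
    sample_id = x$samples$sample_id,
    group = x$samples$group,
    shannon = apply(x$values, 1, shannon, base = base)
  )
}

#' Bray-Curtis dissimilarity between two samples
#'
#' 1 - 2 * sum min(x_i, y_i) / (sum x + sum y), in \[0, 1\].
#'
#' @param x,y Non-negative numeric vectors of equal length, not both all
#'   zero.
#' @return Bray-Curtis distance.
#' @export
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (any(x < 0) || any(y < 0)) abort("negative abundances")
  s <- sum(x) + sum(y)
  if (s == 0) abort("both samples are all-zero")
  1 - 2 * sum(pmin(x, y)) / s
}

#' All-pairs Bray-Curtis distance matrix
#'
#' @param x A `feature_table` of non-negative abundances.
#' @return A `distance_matrix`: symmetric matrix with zero diagonal, sample
#'   ids as dimnames, plus the sample metadata as an attribute.
#' @export
bray_curtis_matrix <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  v <- x$values
  n <- nrow(v)
  d <- matrix(0, n, n, dimnames = list(rownames(v), rownames(v)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- bray_curtis(v[i, ], v[j, ])
    }
  }
  distance_matrix(d, x$samples)
}

#' Construct a validated distance matrix
#'
#' @param values Symmetric non-negative matrix with zero diagonal and
#'   sample ids as dimnames.
#' @param samples Sample metadata tibble aligned with the dimnames.
#' @return A `distance_matrix` object.
#' @export
distance_matrix <- function(values, samples) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) abort("distance matrix needs sample ids as dimnames")
  if (!isTRUE(all.equal(values, t(values), tolerance = 1e-12))) {
    abort("distance matrix is not symmetric")
  }
  if (any(abs(diag(values)) > 1e-12)) abort("distance matrix diagonal is not zero")
  if (any(values < 0)) abort("negative distances")
  if (any(!is.finite(values))) abort("non-finite distances")
  samples <- as_tibble(samples)
  samples <- samples[match(rownames(values), samples$sample_id), , drop = FALSE]
  if (anyNA(samples$sample_id)) abort("sample metadata does not cover all distance rows")
  structure(values, class = c("distance_matrix", "matrix", "array"),
            samples = samples)
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> %d samples\n", nrow(x)))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x))), drop = FALSE])
  invisible(x)
}
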