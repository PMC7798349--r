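# Independent brute-force oracles, deliberately written with different
# machinery than the package (recursive permutation generation, direct
# formula evaluation), plus small fixture builders.

# all permutations of seq_len(n), recursively (list-free, independent of
# the package's iterative constructor)
oracle_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- oracle_perms(n - 1)
  out <- NULL
  for (k in seq_len(n)) {
    shifted <- sub
    shifted[sub >= k] <- shifted[sub >= k] + 1L
    out <- rbind(out, cbind(rep(k, nrow(sub)), shifted))
  }
  out
}

# brute-force two-sided exact Spearman p by enumerating permutations of y
oracle_spearman_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  obs <- abs(cor(rx, ry))
  pm <- oracle_perms(n)
  vals <- apply(pm, 1, function(pi) abs(cor(rx, ry[pi])))
  mean(vals >= obs - 1e-12)
}

# brute-force exact two-sided Mann-Whitney p over all group assignments
oracle_mw_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  u_of <- function(ix) sum(rk[ix]) - n1 * (n1 + 1) / 2
  center <- n1 * (n - n1) / 2
  obs <- abs(u_of(seq_len(n1)) - center)
  devs <- apply(combn(n, n1), 2, function(ix) abs(u_of(ix) - center))
  mean(devs >= obs - 1e-9)
}

# direct ANOSIM R from its definition
oracle_anosim_r <- function(d, groups) {
  n <- nrow(d)
  low <- lower.tri(d)
  rk <- matrix(0, n, n)
  rk[low] <- rank(d[low])
  rk <- rk + t(rk)
  same <- outer(groups, groups, "==")
  (mean(rk[low & !same]) - mean(rk[low & same])) / (n * (n - 1) / 4)
}

# brute-force ANOSIM p over all distinct 2-group relabelings
oracle_anosim_p <- function(d, groups) {
  n <- nrow(d)
  n1 <- sum(groups == groups[1])
  obs <- oracle_anosim_r(d, groups)
  rs <- apply(combn(n, n1), 2, function(ix) {
    g <- rep("b", n); g[ix] <- "a"
    oracle_anosim_r(d, g)
  })
  mean(rs >= obs - 1e-12)
}

# brute-force permutation p for a correlation difference over all splits
oracle_diff_p <- function(x1, y1, x2, y2) {
  xx <- c(x1, x2); yy <- c(y1, y2)
  n <- length(xx); n1 <- length(x1)
  safe_rho <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) return(0)
    cor(rank(a), rank(b))
  }
  obs <- abs(safe_rho(x2, y2) - safe_rho(x1, y1))
  ds <- apply(combn(n, n1), 2, function(ix) {
    abs(safe_rho(xx[-ix], yy[-ix]) - safe_rho(xx[ix], yy[ix]))
  })
  mean(ds >= obs - 1e-12)
}

# minimal 2-group feature table fixture
tiny_table <- function(values, type = "taxon", compartment = "cecum",
                       kind = "counts", species = NA_character_) {
  n <- nrow(values)
  stopifnot(n %% 2 == 0)
  md <- tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(n)),
    group = rep(c("control", "berberine"), each = n / 2),
    sex = rep(c("M", "F"), length.out = n)
  )
  if (is.null(colnames(values))) colnames(values) <- paste0("f", seq_len(ncol(values)))
  rownames(values) <- md$sample_id
  ft <- tibble::tibble(
    feature_id = colnames(values),
    feature_type = type, compartment = compartment, species = species
  )
  feature_table(values, md, ft, kind = kind)
}

# small bile-acid panel fixture with class annotations
tiny_panel <- function(conc, conjugation, origin, sulfated,
                       compartment = "cecum") {
  n <- nrow(conc)
  md <- tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(n)),
    group = rep(c("control", "berberine"), length.out = n),
    sex = "M"
  )
  md <- md[order(md$sample_id), ]
  if (is.null(colnames(conc))) colnames(conc) <- paste0("ba", seq_len(ncol(conc)))
  rownames(conc) <- md$sample_id
  ft <- tibble::tibble(
    feature_id = colnames(conc), feature_type = "bile_acid",
    compartment = compartment, species = NA_character_,
    conjugation = conjugation, origin = origin, sulfated = sulfated
  )
  feature_table(conc, md, ft, kind = "concentrations")
}
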