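#' Built-in bile acid analyte registry
#'
#' Annotation table for the analytes the package knows about: conjugation
#' state (unconjugated / taurine / glycine), origin (primary bile acids made
#' by the host liver vs. secondary products of microbial metabolism such as
#' 7alpha-dehydroxylation) and sulfation. The `control_mean_*` columns are
#' the per-analyte location parameters the synthetic generator uses for each
#' compartment (cecum/liver in umol per g, serum in umol per L).
#'
#' @return Tibble with one row per analyte.
#' @export
ba_registry <- function() {
  tibble::tribble(
    ~analyte_id, ~conjugation,   ~origin,     ~sulfated, ~control_mean_cecum, ~control_mean_liver, ~control_mean_serum,
    "CA",        "unconjugated", "primary",   FALSE,     0.45,   0.020,  0.60,
    "bMCA",      "unconjugated", "primary",   FALSE,     0.30,   0.015,  0.40,
    "UCA",       "unconjugated", "primary",   FALSE,     0.05,   0.002,  0.05,
    "7-oxo-CA",  "unconjugated", "primary",   FALSE,     0.05,   0.002,  0.05,
    "CDCA",      "unconjugated", "primary",   FALSE,     0.08,   0.004,  0.10,
    "DCA",       "unconjugated", "secondary", FALSE,     0.22,   0.010,  0.30,
    "LCA",       "unconjugated", "secondary", FALSE,     0.04,   0.002,  0.04,
    "TCA",       "taurine",      "primary",   FALSE,     0.04,   3.50,   1.20,
    "TbMCA",     "taurine",      "primary",   FALSE,     0.02,   2.00,   0.80,
    "TCDCA",     "taurine",      "primary",   FALSE,     0.01,   0.60,   0.30,
    "GCA",       "glycine",      "primary",   FALSE,     0.005,  0.15,   0.10,
    "TDCA",      "taurine",      "secondary", FALSE,     0.01,   0.40,   0.25,
    "TLCA",      "taurine",      "secondary", FALSE,     0.003,  0.05,   0.03,
    "DCA-3S",    "unconjugated", "secondary", TRUE,      0.005,  0.01,   0.02,
    "LCA-3S",    "unconjugated", "secondary", TRUE,      0.003,  0.005,  0.01,
    "TLCA-3S",   "taurine",      "secondary", TRUE,      0.004,  0.01,   0.01
  )
}

#' Internal-standard quantitation
#'
#' Single-point quantitation against a deuterated internal standard spiked
#' at a known amount (the assay adds d4-CA, d4-GCA and d4-TCA at
#' 100 nmol/ml): concentration = (analyte area / IS area) x IS amount /
#' sample mass, with nmol converted to umol. A per-analyte response factor
#' (default 1) rescales the area ratio when calibration data exist.
#'
#' @param analyte_area Non-negative peak area(s).
#' @param is_area Positive internal-standard peak area(s).
#' @param is_amount_nmol Internal standard amount in nmol (default 100).
#' @param sample_mass Sample mass in g (cecum, liver) or volume in L
#'   (serum).
#' @param response_factor Analyte/IS response factor (default 1).
#' @return Concentration(s) in umol per g (or umol per L).
#' @export
quantify_from_is <- function(analyte_area, is_area, is_amount_nmol = 100,
                             sample_mass = 1, response_factor = 1) {
  if (any(analyte_area < 0)) abort("negative analyte peak area")
  if (any(is_area <= 0)) abort("internal standard not detected (is_area <= 0)")
  if (any(sample_mass <= 0)) abort("sample_mass must be positive")
  (analyte_area / is_area) / response_factor * is_amount_nmol / 1000 / sample_mass
}

#' Per-sample total bile acids
#'
#' @param panel A bile-acid `feature_table` (concentrations).
#' @return Tibble with `sample_id`, `group`, `total` (same units as the
#'   panel).
#' @export
total_bile_acids <- function(panel) {
  stopifnot(inherits(panel, "feature_table"))
  if (ncol(panel$values) == 0) abort("empty panel")
  tibble(
    sample_id = panel$samples$sample_id,
    group = panel$samples$group,
    total = unname(rowSums(panel$values))
  )
}

#' Per-sample bile acid class totals
#'
#' Sums analyte concentrations within classes (conjugation state, origin, or
#' sulfation). Class totals conserve mass: per sample they sum exactly to
#' [total_bile_acids()].
#'
#' @param panel A bile-acid `feature_table` whose features carry the
#'   class column requested.
#' @param by `"conjugation"`, `"origin"` or `"sulfated"`.
#' @return Tibble with `sample_id`, `group`, `class`, `total`.
#' @export
ba_class_summary <- function(panel, by = c("conjugation", "origin", "sulfated")) {
  stopifnot(inherits(panel, "feature_table"))
  by <- match.arg(by)
  if (!by %in% names(panel$features)) {
    abort(paste0("panel features have no '", by, "' annotation"))
  }
  cls <- panel$features[[by]]
  if (anyNA(cls)) abort(paste("some analytes are not annotated for", by))
  as_tibble(panel) |>
    group_by(.data$sample_id, .data$group, class = as.character(.data[[by]])) |>
    summarise(total = sum(.data$value), .groups = "drop")
}

#' Two-group comparison of a numeric outcome
#'
#' Welch's t test, or an exact Mann-Whitney (rank-sum) test whose two-sided
#' p-value is computed by enumerating all `choose(n1+n2, n1)` assignments of
#' the pooled observations to groups when the total n is at most 12 (ties
#' handled by midranks); larger samples fall back to the normal
#' approximation with tie correction.
#'
#' @param x,y Numeric vectors (each length >= 2).
#' @param test `"welch_t"` or `"mann_whitney_exact"`.
#' @return One-row tibble: `statistic`, `p_value`, `method`.
#' @export
compare_groups <- function(x, y, test = c("welch_t", "mann_whitney_exact")) {
  test <- match.arg(test)
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (test == "welch_t") {
    if (sd(c(x, y)) == 0 || (sd(x) == 0 && sd(y) == 0)) {
      warn("constant data: t statistic undefined, returning p = 1")
      return(tibble(statistic = NA_real_, p_value = 1, method = "welch_t"))
    }
    fit <- t.test(x, y)
    return(tibble(statistic = unname(fit$statistic), p_value = fit$p.value,
                  method = "welch_t"))
  }
  mann_whitney_exact(x, y)
}

mw_u <- function(rk, in_x, n1, n2) {
  sum(rk[in_x]) - n1 * (n1 + 1) / 2
}

mann_whitney_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  rk <- rank(pooled)
  u_obs <- mw_u(rk, seq_len(n1), n1, n2)
  center <- n1 * n2 / 2
  if (n <= 12) {
    sel <- subset_indicators(n, n1)
    u_all <- as.vector(sel %*% rk) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - center) >= abs(u_obs - center) - 1e-9)
    method <- "mann_whitney_exact"
  } else {
    ties <- table(rk)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (u_obs - center) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "mann_whitney_normal"
  }
  tibble(statistic = unname(u_obs), p_value = p, method = method)
}
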