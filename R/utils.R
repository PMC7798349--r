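#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows bind_cols rename distinct pull n across all_of
#' @importFrom stats cor sd var qnorm pnorm pt rnorm rnbinom rlnorm rmultinom
#'   setNames p.adjust t.test isoreg cmdscale dist optim quantile rbinom runif
#' @importFrom utils combn head
NULL

GROUP_LEVELS <- c("control", "berberine")
FEATURE_TYPES <- c("transcript", "bile_acid", "taxon")
COMPARTMENTS <- c("cecum", "liver", "serum", "none")

#' Seven-member defined gut bacterial consortium
#'
#' Species names of the defined minimal community used throughout the
#' package (four Bacteroidetes-related members and three Firmicutes capable
#' of complete bile acid metabolism including 7alpha-dehydroxylation).
#'
#' @return Character vector of 7 species names.
#' @export
consortium_species <- function() {
  c(
    "Bacteroides_vulgatus", "Bacteroides_uniformis", "Parabacteroides_distasonis",
    "Bilophila_wadsworthia", "Clostridium_hylemonae", "Clostridium_hiranonis",
    "Blautia_producta"
  )
}

# all k-subsets of n as a logical matrix (choose(n,k) x n); used for full
# enumeration of two-group label assignments
subset_indicators <- function(n, k) {
  cmb <- combn(n, k)
  m <- matrix(FALSE, ncol(cmb), n)
  m[cbind(rep(seq_len(ncol(cmb)), each = k), as.vector(cmb))] <- TRUE
  m
}

# all permutations of 1..n as an (n! x n) integer matrix, built
# incrementally; n is capped by callers (exact tests use n <= 9)
permutation_matrix <- function(n) {
  stopifnot(n >= 1, n <= 9)
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  p <- matrix(1L, 1L, 1L)
  if (n > 1) {
    for (m in 2:n) {
      blocks <- lapply(seq_len(m), function(k) {
        shifted <- p + (p >= k)
        cbind(rep(k, nrow(p)), shifted)
      })
      p <- do.call(rbind, blocks)
    }
  }
  storage.mode(p) <- "integer"
  .perm_cache[[key]] <- p
  p
}

.perm_cache <- new.env(parent = emptyenv())

check_group_labels <- function(groups) {
  groups <- as.character(groups)
  bad <- setdiff(unique(groups), GROUP_LEVELS)
  if (length(bad) > 0) {
    abort(paste0(
      "group labels must be one of ", paste(GROUP_LEVELS, collapse = ", "),
      "; found: ", paste(bad, collapse = ", ")
    ))
  }
  factor(groups, levels = GROUP_LEVELS)
}

# deterministic child seed derived from a user seed and a stream label;
# kept below 2^31
derive_seed <- function(seed, stream) {
  offs <- sum(utf8ToInt(stream)) %% 1000L
  (as.integer(seed) * 1009L + offs * 7L) %% 214748329L
}
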