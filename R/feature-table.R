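#' Construct a feature table
#'
#' The central container of the pipeline: a non-negative numeric matrix of
#' samples (rows) by features (columns), with a sample-metadata tibble
#' (`sample_id`, `group`, `sex`) and a feature-annotation tibble
#' (`feature_id`, `feature_type`, `compartment`, `species`, plus any extra
#' analyte annotation columns). Counts (taxa, transcripts) and
#' concentrations (bile acids) share this container so that all compartments
#' can be merged into the single table the correlation networks run on.
#'
#' Samples are stored in canonical order (sorted by `sample_id`); features
#' keep their given order.
#'
#' @param values Numeric matrix, samples x features, non-negative. Row names
#'   are sample ids, column names feature ids (set from the metadata if
#'   absent).
#' @param samples Tibble/data frame with columns `sample_id`, `group`
#'   (`"control"` or `"berberine"`), `sex` (`"M"`/`"F"`).
#' @param features Tibble/data frame with columns `feature_id`,
#'   `feature_type` (`"transcript"`, `"bile_acid"` or `"taxon"`),
#'   `compartment` (`"cecum"`, `"liver"`, `"serum"` or `"none"`) and
#'   `species` (`NA` except for transcripts). Extra columns are carried
#'   along unchanged.
#' @param kind `"counts"` (values must be non-negative integers) or
#'   `"concentrations"` (non-negative reals).
#'
#' @return A `feature_table` object.
#' @export
feature_table <- function(values, samples, features,
                          kind = c("counts", "concentrations")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  samples <- as_tibble(samples)
  features <- as_tibble(features)

  required_s <- c("sample_id", "group", "sex")
  if (!all(required_s %in% names(samples))) {
    abort(paste("sample metadata must have columns:", paste(required_s, collapse = ", ")))
  }
  required_f <- c("feature_id", "feature_type", "compartment", "species")
  missing_f <- setdiff(required_f, names(features))
  if ("species" %in% missing_f) features$species <- NA_character_
  if ("compartment" %in% missing_f) features$compartment <- "none"
  missing_f <- setdiff(required_f, names(features))
  if (length(missing_f) > 0) {
    abort(paste("feature annotations must have columns:", paste(missing_f, collapse = ", ")))
  }

  if (anyDuplicated(samples$sample_id)) {
    abort(paste("duplicated sample_id:", samples$sample_id[duplicated(samples$sample_id)][1]))
  }
  if (anyDuplicated(features$feature_id)) {
    abort(paste("duplicated feature_id:", features$feature_id[duplicated(features$feature_id)][1]))
  }
  if (nrow(values) != nrow(samples) || ncol(values) != nrow(features)) {
    abort(sprintf(
      "values is %d x %d but there are %d samples and %d features",
      nrow(values), ncol(values), nrow(samples), nrow(features)
    ))
  }
  if (is.null(rownames(values))) rownames(values) <- samples$sample_id
  if (is.null(colnames(values))) colnames(values) <- features$feature_id
  if (!identical(rownames(values), samples$sample_id)) {
    abort("row names of values do not match sample metadata order")
  }
  if (!identical(colnames(values), features$feature_id)) {
    abort("column names of values do not match feature annotation order")
  }

  samples$group <- check_group_labels(samples$group)
  bad_sex <- setdiff(unique(as.character(samples$sex)), c("M", "F"))
  if (length(bad_sex) > 0) abort(paste("sex must be M or F; found:", paste(bad_sex, collapse = ", ")))
  samples$sex <- as.character(samples$sex)

  bad_type <- setdiff(unique(features$feature_type), FEATURE_TYPES)
  if (length(bad_type) > 0) {
    abort(paste("unknown feature_type:", paste(bad_type, collapse = ", ")))
  }
  bad_comp <- setdiff(unique(features$compartment), COMPARTMENTS)
  if (length(bad_comp) > 0) {
    abort(paste("unknown compartment:", paste(bad_comp, collapse = ", ")))
  }
  tr <- features$feature_type == "transcript"
  if (any(tr & (is.na(features$species) | features$compartment != "cecum"))) {
    abort("transcripts must have species set and compartment 'cecum'")
  }
  if (any(features$feature_type == "bile_acid" &
          !features$compartment %in% c("cecum", "liver", "serum"))) {
    abort("bile acids must have compartment cecum, liver or serum")
  }
  if (any(features$feature_type == "taxon" & features$compartment != "cecum")) {
    abort("taxa must have compartment 'cecum'")
  }

  if (!is.numeric(values)) abort("values must be numeric")
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "missing value at sample '%s', feature '%s' (missing values are not permitted; write undetected analytes as 0)",
      rownames(values)[idx[1]], colnames(values)[idx[2]]
    ))
  }
  if (any(values < 0)) {
    idx <- which(values < 0, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "negative value at sample '%s', feature '%s'",
      rownames(values)[idx[1]], colnames(values)[idx[2]]
    ))
  }
  if (kind == "counts") {
    if (any(values != round(values))) {
      idx <- which(values != round(values), arr.ind = TRUE)[1, ]
      abort(sprintf(
        "non-integer count at sample '%s', feature '%s'",
        rownames(values)[idx[1]], colnames(values)[idx[2]]
      ))
    }
    if (max(values) < .Machine$integer.max) storage.mode(values) <- "integer"
  }

  ord <- order(samples$sample_id)
  samples <- samples[ord, , drop = FALSE]
  values <- values[ord, , drop = FALSE]

  structure(
    list(values = values, samples = samples, features = features, kind = kind),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> %d samples x %d features (%s)\n",
    nrow(x$values), ncol(x$values), x$kind
  ))
  tab <- table(x$features$feature_type)
  cat("  features:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  groups:  ", paste(sprintf(
    "%s=%d", levels(x$samples$group), tabulate(x$samples$group, 2)
  ), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Long-format view of a feature table
#'
#' @param x A `feature_table`.
#' @param ... Unused.
#' @return Tibble with one row per (sample, feature) cell, joined with
#'   sample metadata and feature annotations.
#' @export
as_tibble.feature_table <- function(x, ...) {
  long <- tibble(
    sample_id = rep(rownames(x$values), times = ncol(x$values)),
    feature_id = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values)
  )
  long |>
    left_join(x$samples, by = "sample_id") |>
    left_join(x$features, by = "feature_id")
}

#' Subset a feature table to one treatment group
#'
#' @param x A `feature_table`.
#' @param group `"control"` or `"berberine"`.
#' @return A `feature_table` containing only that group's samples.
#' @export
filter_group <- function(x, group) {
  stopifnot(inherits(x, "feature_table"))
  group <- match.arg(group, GROUP_LEVELS)
  keep <- x$samples$group == group
  if (!any(keep)) abort(paste("no samples in group", group))
  feature_table(
    x$values[keep, , drop = FALSE],
    x$samples[keep, , drop = FALSE],
    x$features,
    kind = x$kind
  )
}

#' Merge compartment tables into the single feature table
#'
#' Column-binds several feature tables measured on the same mice
#' (transcripts, taxa, bile acid panels from each compartment) into the one
#' table all-pairs correlations run on. Feature ids are prefixed with
#' compartment (and species for transcripts) so ids stay unique; the
#' original id is kept in a `source_id` annotation column.
#'
#' @param tables List of `feature_table` objects over an identical sample
#'   set.
#' @return A `feature_table` of kind `"concentrations"` (mixed value types
#'   after merging) whose feature count is the sum of the inputs'.
#' @export
combine_features <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1)
  purrr::walk(tables, function(t) stopifnot(inherits(t, "feature_table")))

  ids <- lapply(tables, function(t) sort(t$samples$sample_id))
  ref <- ids[[1]]
  for (i in seq_along(ids)[-1]) {
    if (!identical(ids[[i]], ref)) {
      d <- union(setdiff(ids[[i]], ref), setdiff(ref, ids[[i]]))
      abort(paste0(
        "tables do not share an identical sample set; symmetric difference: ",
        paste(d, collapse = ", ")
      ))
    }
  }

  pieces <- purrr::map(tables, function(t) {
    f <- t$features
    prefix <- ifelse(
      f$feature_type == "transcript",
      paste(f$compartment, f$species, sep = "|"),
      paste(f$compartment, f$feature_type, sep = "|")
    )
    new_id <- paste(prefix, f$feature_id, sep = "|")
    f$source_id <- f$feature_id
    f$feature_id <- new_id
    v <- t$values[ref, , drop = FALSE]
    colnames(v) <- new_id
    list(values = v, features = f)
  })

  values <- do.call(cbind, purrr::map(pieces, "values"))
  features <- bind_rows(purrr::map(pieces, "features"))
  if (anyDuplicated(features$feature_id)) {
    abort(paste(
      "feature ids still duplicated after prefixing:",
      features$feature_id[duplicated(features$feature_id)][1]
    ))
  }
  samples <- tables[[1]]$samples |> arrange(.data$sample_id)
  feature_table(values, samples, features, kind = "concentrations")
}
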