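#' Read a feature table from TSV
#'
#' Files are feature x sample (the usual 16S / RNA-Seq table dialect): first
#' column feature ids, header row sample ids. In memory the table is
#' transposed to the samples x features canonical orientation.
#'
#' @param path TSV file path.
#' @param metadata Sample metadata tibble (from [read_sample_metadata()]) or
#'   a path to the metadata TSV.
#' @param kind `"counts"` or `"concentrations"`.
#' @param annotations Optional feature-annotation tibble keyed by
#'   `feature_id`; features absent from it get `feature_type`/`compartment`
#'   from `default_type`/`default_compartment`.
#' @param default_type,default_compartment,default_species Annotation
#'   defaults applied to features not covered by `annotations`.
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path, metadata, kind = c("counts", "concentrations"),
                               annotations = NULL,
                               default_type = "taxon",
                               default_compartment = "cecum",
                               default_species = NA_character_) {
  kind <- match.arg(kind)
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (ncol(raw) < 2) abort(paste("no sample columns in", path))
  feature_id <- raw[[1]]
  if (anyDuplicated(feature_id)) {
    abort(paste("duplicated feature id in", path, ":",
                feature_id[duplicated(feature_id)][1]))
  }
  num <- as.matrix(raw[, -1, drop = FALSE])
  suppressWarnings(storage.mode(num) <- "double")
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "non-numeric cell in %s at feature '%s', sample '%s'",
      path, feature_id[idx[1]], colnames(num)[idx[2]]
    ))
  }
  rownames(num) <- feature_id

  if (is.character(metadata)) metadata <- read_sample_metadata(metadata)
  metadata <- as_tibble(metadata)
  miss <- setdiff(colnames(num), metadata$sample_id)
  if (length(miss) > 0) {
    abort(paste("samples missing from metadata:", paste(miss, collapse = ", ")))
  }
  metadata <- metadata |> filter(.data$sample_id %in% colnames(num))

  feats <- tibble(
    feature_id = feature_id,
    feature_type = default_type,
    compartment = default_compartment,
    species = default_species
  )
  if (!is.null(annotations)) {
    annotations <- as_tibble(annotations)
    keep <- intersect(names(annotations), c("feature_id", "feature_type",
                                            "compartment", "species",
                                            "conjugation", "origin", "sulfated"))
    ann <- annotations[, keep, drop = FALSE]
    feats <- feats |>
      dplyr::rows_update(ann[ann$feature_id %in% feats$feature_id,
                             intersect(names(ann), names(feats)), drop = FALSE],
                         by = "feature_id")
    extra <- setdiff(names(ann), names(feats))
    if (length(extra) > 0) {
      feats <- feats |> left_join(ann[, c("feature_id", extra)], by = "feature_id")
    }
  }

  vals <- t(num)[metadata$sample_id, , drop = FALSE]
  feature_table(vals, metadata, feats, kind = kind)
}

#' Write a feature table to TSV (feature x sample)
#'
#' @param x A `feature_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  stopifnot(inherits(x, "feature_table"))
  out <- as.data.frame(t(x$values))
  out <- cbind(feature_id = colnames(x$values), out)
  readr::write_tsv(as_tibble(out), path, progress = FALSE)
  invisible(path)
}

#' Read a sample metadata TSV
#'
#' Expected columns: `sample_id`, `group` (control/berberine), `sex` (M/F).
#'
#' @param path TSV file path.
#' @return Tibble of sample metadata.
#' @export
read_sample_metadata <- function(path) {
  md <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    group = readr::col_character(),
    sex = readr::col_character()
  ), progress = FALSE)
  if (anyDuplicated(md$sample_id)) {
    abort(paste("duplicated sample_id in", path, ":",
                md$sample_id[duplicated(md$sample_id)][1]))
  }
  md$group <- check_group_labels(md$group)
  md
}

#' Write a sample metadata TSV
#' @param metadata Tibble with `sample_id`, `group`, `sex`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(metadata, path) {
  readr::write_tsv(
    metadata |> mutate(group = as.character(.data$group)),
    path, progress = FALSE
  )
  invisible(path)
}
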