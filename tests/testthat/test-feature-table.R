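test_that("TSV round-trip preserves counts exactly and concentrations to 1e-12", {
  md <- tibble::tibble(sample_id = c("B01", "A01"), group = c("berberine", "control"),
                       sex = c("F", "M"))
  vals <- matrix(c(5L, 0L, 3L, 120L, 44L, 7L), nrow = 2,
                 dimnames = list(c("B01", "A01"), c("t1", "t2", "t3")))
  ft <- feature_table(vals, md,
                      tibble::tibble(feature_id = c("t1", "t2", "t3"),
                                     feature_type = "taxon",
                                     compartment = "cecum",
                                     species = NA_character_),
                      kind = "counts")
  # canonical sample order is sorted by id
  expect_identical(rownames(ft$values), c("A01", "B01"))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(ft, path)
  back <- read_feature_table(path, md, kind = "counts")
  expect_identical(back$values, ft$values)

  conc <- matrix(c(pi, exp(1), 1 / 3, 2 / 7), nrow = 2,
                 dimnames = list(c("A01", "B01"), c("CA", "DCA")))
  ft2 <- feature_table(conc, md[order(md$sample_id), ],
                       tibble::tibble(feature_id = c("CA", "DCA"),
                                      feature_type = "bile_acid",
                                      compartment = "cecum",
                                      species = NA_character_),
                       kind = "concentrations")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(ft2, path2)
  back2 <- read_feature_table(path2, md, kind = "concentrations",
                              default_type = "bile_acid")
  expect_equal(back2$values, ft2$values, tolerance = 1e-12)
})

test_that("malformed tables are rejected with informative errors", {
  md <- tibble::tibble(sample_id = c("s1", "s2"), group = c("control", "berberine"),
                       sex = c("M", "F"))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ts1\ts2", "a\t1\t2", "a\t3\t4"), path)
  expect_error(read_feature_table(path, md), "duplicated feature id.*a")

  writeLines(c("feature_id\ts1\ts2", "a\t1\t2", "b\t-3\t4"), path)
  expect_error(read_feature_table(path, md), "negative value")

  writeLines(c("feature_id\ts1\ts2", "a\t1\tx", "b\t3\t4"), path)
  expect_error(read_feature_table(path, md), "non-numeric cell")

  writeLines(c("feature_id\ts1\ts2", "a\t1.5\t2", "b\t3\t4"), path)
  expect_error(read_feature_table(path, md, kind = "counts"), "non-integer count")

  # annotation invariants
  expect_error(
    feature_table(matrix(1, 2, 1, dimnames = list(c("s1", "s2"), "g1")), md,
                  tibble::tibble(feature_id = "g1", feature_type = "transcript",
                                 compartment = "cecum", species = NA_character_)),
    "transcripts must have species"
  )
})

test_that("combine_features concatenates compartments over matched mice", {
  mk <- function(f, type, comp, sp = NA_character_) {
    tiny_table(matrix(seq_len(4 * f) + 0, nrow = 4,
                      dimnames = list(NULL, paste0(comp, "_f", seq_len(f)))),
               type = type, compartment = comp, kind = "concentrations",
               species = sp)
  }
  tr <- mk(12, "transcript", "cecum", "Bilophila_wadsworthia")
  ba_c <- mk(3, "bile_acid", "cecum")
  ba_l <- mk(3, "bile_acid", "liver")
  ba_s <- mk(3, "bile_acid", "serum")

  comb <- combine_features(list(tr, ba_c, ba_l, ba_s))
  expect_equal(ncol(comb$values), 12 + 3 + 3 + 3)
  expect_false(anyDuplicated(comb$features$feature_id) > 0)
  expect_true(all(comb$features$source_id %in%
                    c(colnames(tr$values), colnames(ba_c$values),
                      colnames(ba_l$values), colnames(ba_s$values))))
  # identity case: combining one table keeps values and sample order
  one <- combine_features(list(ba_c))
  expect_equal(unname(one$values), unname(ba_c$values))

  # disjoint samples -> error listing the difference
  other <- ba_c
  other$samples$sample_id <- paste0("x", other$samples$sample_id)
  rownames(other$values) <- other$samples$sample_id
  expect_error(combine_features(list(tr, other)), "symmetric difference")
})

test_that("long-format view joins metadata and annotations", {
  ft <- tiny_table(matrix(1:8, nrow = 4))
  long <- tibble::as_tibble(ft)
  expect_equal(nrow(long), 8)
  expect_true(all(c("sample_id", "feature_id", "value", "group", "sex",
                    "feature_type", "compartment") %in% names(long)))
  sub <- filter_group(ft, "berberine")
  expect_equal(nrow(sub$values), 2)
  expect_true(all(sub$samples$group == "berberine"))
})
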