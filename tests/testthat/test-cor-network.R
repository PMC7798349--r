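fake_records <- function(n, seed = 1) {
  withr::with_seed(seed, {
    ids <- sprintf("f%03d", 1:30)
    pairs <- t(combn(ids, 2))
    k <- sample(nrow(pairs), n)
    tibble::tibble(
      feature_i = pairs[k, 1], feature_j = pairs[k, 2],
      rho = runif(n, -1, 1), n = 6, p = runif(n)^2, group = "control"
    )
  })
}

test_that("edge filtering applies both thresholds on |rho| and p", {
  rec <- tibble::tibble(
    feature_i = c("a", "a", "b"), feature_j = c("b", "c", "c"),
    rho = c(0.65, 0.95, -0.8), n = 6, p = c(0.001, 0.04, 0.01),
    group = "control"
  )
  net <- build_network(rec)
  expect_equal(nrow(net$edges), 2) # 0.65 fails rho_min despite tiny p
  expect_setequal(net$edges$feature_j, "c")
  expect_true("negative" %in% net$edges$sign)
  empty <- build_network(rec[0, ])
  expect_equal(nrow(empty$edges), 0)
  expect_equal(nrow(empty$nodes), 0)
})

test_that("filtering is monotone in the thresholds", {
  rec <- fake_records(200, seed = 2)
  base <- nrow(build_network(rec, 0.5, 0.1)$edges)
  for (rho_min in c(0.6, 0.8, 0.95)) {
    for (p_max in c(0.05, 0.01)) {
      n_edges <- nrow(build_network(rec, rho_min, p_max)$edges)
      expect_lte(n_edges, base)
    }
  }
  # nested thresholds nest edge sets
  e1 <- build_network(rec, 0.7, 0.05)$edges
  e2 <- build_network(rec, 0.8, 0.01)$edges
  key <- function(e) paste(e$feature_i, e$feature_j)
  expect_true(all(key(e2) %in% key(e1)))
})

test_that("topology metrics satisfy graph identities", {
  empty <- build_network(fake_records(5)[0, ])
  topo0 <- network_topology(empty)
  expect_equal(topo0$n_nodes, 0L)
  expect_equal(topo0$n_edges, 0L)
  expect_equal(topo0$density, 0)

  # complete graph on 4 nodes
  k4 <- tibble::tibble(
    feature_i = c("a", "a", "a", "b", "b", "c"),
    feature_j = c("b", "c", "d", "c", "d", "d"),
    rho = 0.9, n = 6, p = 0.001, group = "control"
  )
  net <- build_network(k4)
  topo <- network_topology(net)
  expect_equal(topo$density, 1)
  expect_equal(topo$n_components, 1L)

  rec <- fake_records(120, seed = 3)
  net2 <- build_network(rec, 0.5, 0.2)
  deg <- network_degrees(net2)
  expect_equal(sum(deg$degree), 2 * nrow(net2$edges)) # handshake lemma
})

test_that("sub-networks are induced neighborhoods of the focal feature", {
  star <- tibble::tibble(
    feature_i = rep("hub", 4), feature_j = c("s1", "s2", "s3", "s4"),
    rho = 0.9, n = 6, p = 0.001, group = "control"
  )
  chain <- tibble::tibble(
    feature_i = c("s4", "t1"), feature_j = c("t1", "t2"),
    rho = 0.9, n = 6, p = 0.001, group = "control"
  )
  net <- build_network(dplyr::bind_rows(star, chain))
  expect_equal(nrow(subnetwork(net, "hub", 0)$edges), 0)
  expect_equal(nrow(subnetwork(net, "hub", 0)$nodes), 1)
  s1 <- subnetwork(net, "hub", 1)
  expect_setequal(s1$nodes$feature_id, c("hub", "s1", "s2", "s3", "s4"))
  expect_equal(nrow(s1$edges), 4)
  whole <- subnetwork(net, "hub", 10)
  expect_equal(nrow(whole$nodes), nrow(net$nodes)) # one component
  expect_error(subnetwork(net, "absent"), "not in network")
})

test_that("exports round-trip through standard graph formats", {
  rec <- fake_records(40, seed = 4)
  ann <- tibble::tibble(
    feature_id = sprintf("f%03d", 1:30),
    feature_type = rep(c("transcript", "bile_acid", "taxon"), 10),
    compartment = "cecum", species = NA_character_
  )
  net <- build_network(rec, 0.5, 0.2, annotations = ann)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  sif <- withr::local_tempfile(fileext = ".sif")
  write_edge_list(net, tsv)
  write_graphml(net, gml)
  write_sif(net, sif)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(net$edges))
  ig <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(ig), nrow(net$nodes))
  expect_equal(igraph::gsize(ig), nrow(net$edges))
  sif_lines <- readLines(sif)
  expect_equal(length(sif_lines) >= nrow(net$edges), TRUE)
  expect_true(all(grepl("correlation", sif_lines[seq_len(nrow(net$edges))])))
})
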