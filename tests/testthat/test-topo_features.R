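# P3 path graph A-B-C and friends are reused across cases
p3 <- graph_from_spec(c("A-B", "B-C"))
triangle <- graph_from_spec(c("A-B", "B-C", "C-A"))
star <- graph_from_spec(c("H-L1", "H-L2", "H-L3", "H-L4"))

test_that("degree, disease-neighbor count and ratio match hand values", {
  expect_equal(degree_of(triangle, "A"), 2L)
  expect_equal(degree_of(star, "H"), 4L)
  expect_equal(degree_of(star, "L1"), 1L)
  iso <- graph_from_spec("A-B", extra_nodes = "Z")
  expect_equal(degree_of(iso, "Z"), 0L)
  expect_error(degree_of(star, "nope"), "unknown gene")

  expect_equal(disease_neighbor_count(star, "H", c("L1", "L3")), 2L)
  expect_equal(disease_neighbor_count(star, "H", character()), 0L)
  expect_equal(disease_neighbor_count(p3, "B", c("A", "C")), 2L)
  # self-exclusion only removes the gene itself
  expect_equal(disease_neighbor_count(p3, "B", c("A", "B", "C"),
                                      exclude_self = TRUE), 2L)

  expect_equal(disease_neighbor_ratio(star, "H", c("L1", "L3")), 0.5)
  expect_equal(disease_neighbor_ratio(star, "H", c("L1", "L2", "L3", "L4")), 1)
  expect_equal(disease_neighbor_ratio(iso, "Z", "A"), 0)
})

test_that("betweenness matches hand-enumerated shortest paths", {
  b <- betweenness_all(p3)
  expect_equal(unname(b[c("A", "B", "C")]), c(0, 1, 0))
  # C4: two shortest paths between opposite corners, half credit each
  c4 <- graph_from_spec(c("A-B", "B-C", "C-D", "D-A"))
  expect_equal(unname(betweenness_all(c4)), rep(0.5, 4), tolerance = 1e-12)
  expect_error(betweenness_all(igraph::make_empty_graph(0)), "empty")
})

test_that("clustering coefficient matches the neighbor-edge ratio", {
  expect_equal(clustering_coefficient(triangle, "A"), 1)
  expect_equal(clustering_coefficient(star, "H"), 0)
  g <- graph_from_spec(c("v-a", "v-b", "v-c", "a-b"))
  expect_equal(clustering_coefficient(g, "v"), 1 / 3)
})

test_that("mean shortest path to disease genes handles reachability", {
  expect_equal(mean_shortest_path_to_disease(p3, "B", c("A", "C")), 1)
  expect_equal(mean_shortest_path_to_disease(p3, "A", "B"), 1)
  twocomp <- graph_from_spec(c("A-B", "X-Y"))
  expect_true(is.na(mean_shortest_path_to_disease(twocomp, "X", c("A", "B"))))
  expect_error(mean_shortest_path_to_disease(p3, "A", "A"), "empty")
})

test_that("build_feature_matrix reproduces hand-computed rows on P3", {
  m <- build_feature_matrix(p3, c("A", "B", "C"), c("A", "C"))
  rb <- m[m$gene == "B", ]
  expect_equal(rb$D, 2)
  expect_equal(rb$N, 2)
  expect_equal(rb$R, 1)
  expect_equal(rb$B, 1)
  expect_equal(rb$C, 0)
  expect_equal(rb$M, 1)
  # leave-one-out: A is a disease gene, so its M is the distance to C only
  expect_equal(m[m$gene == "A", "M"], 2)
  # without leave-one-out, A's own distance 0 enters the mean
  m0 <- build_feature_matrix(p3, "A", c("A", "C"), leave_one_out = FALSE)
  expect_equal(m0$M, 1)

  single <- build_feature_matrix(p3, c("A", "B"), "C", features = "D")
  expect_identical(attr(single, "features"), "D")
  expect_identical(names(single), c("gene", "D"))
})

test_that("unreachable genes get M imputed as max finite M + 1", {
  g <- graph_from_spec(c("A-B", "B-C", "X-Y"))
  # leave_one_out off: A (the disease gene itself) keeps a finite M of 0
  expect_message(m <- build_feature_matrix(g, c("A", "B", "C", "X", "Y"), "A",
                                           leave_one_out = FALSE),
                 "imputed")
  expect_equal(attr(m, "n_imputed"), 2L)
  maxfin <- max(m$M[m$gene %in% c("A", "B", "C")])
  expect_equal(m$M[m$gene == "X"], maxfin + 1)
  expect_error(build_feature_matrix(g, c("X", "Y"), "A"), "M undefined")
})

test_that("B, C and M agree with the brute-force oracle on random graphs", {
  set.seed(77)
  for (rep in 1:20) {
    rg <- random_test_graph(sample(5:25, 1L), stats::runif(1, 0.1, 0.4))
    b <- betweenness_all(rg$graph)[rg$nodes]
    expect_equal(unname(b), unname(oracle_betweenness(rg$adj)[rg$nodes]),
                 tolerance = 1e-9)
    disease <- sample(rg$nodes, 3L)
    v <- sample(rg$nodes, 1L)
    expect_equal(clustering_coefficient(rg$graph, v),
                 oracle_clustering(rg$adj, v), tolerance = 1e-12)
    got <- tryCatch(mean_shortest_path_to_disease(rg$graph, v, disease),
                    error = function(e) NA_real_)
    expect_equal(got, oracle_mean_sp(rg$adj, v, setdiff(disease, v)),
                 tolerance = 1e-12)
  }
})

test_that("feature invariants hold on random graphs", {
  set.seed(88)
  for (rep in 1:10) {
    rg <- random_test_graph(20L, 0.2)
    disease <- sample(rg$nodes, 4L)
    m <- suppressMessages(
      build_feature_matrix(rg$graph, rg$nodes, disease))
    expect_true(all(m$R >= 0 & m$R <= 1))
    expect_true(all(m$C >= 0 & m$C <= 1))
    expect_true(all(m$N <= m$D))
    # adding an edge never decreases endpoint degree
    nonadj <- which(!igraph::are_adjacent(rg$graph, rg$nodes[1], rg$nodes[2]))
    g2 <- igraph::add_edges(rg$graph,
                            match(c(rg$nodes[1], rg$nodes[2]),
                                  igraph::V(rg$graph)$name))
    expect_gte(igraph::degree(g2)[rg$nodes[1]],
               igraph::degree(rg$graph)[rg$nodes[1]])
    # removing a disease gene never increases any N
    m2 <- suppressMessages(
      build_feature_matrix(rg$graph, rg$nodes, disease[-1]))
    expect_true(all(m2$N <= m$N))
    # disease = exactly the neighborhood of a non-isolated gene
    v <- rg$nodes[which(igraph::degree(rg$graph)[rg$nodes] > 0)[1]]
    if (!is.na(v)) {
      nb <- names(igraph::neighbors(rg$graph, v))
      expect_equal(disease_neighbor_ratio(rg$graph, v, nb), 1)
      expect_equal(mean_shortest_path_to_disease(rg$graph, v, nb), 1)
    }
  }
})

test_that("betweenness mass equals summed fractional interior path length", {
  # sum over v of B(v) = sum over reachable unordered pairs of (d(s,t) - 1)
  set.seed(99)
  for (rep in 1:5) {
    rg <- random_test_graph(12L, 0.25)
    b <- betweenness_all(rg$graph)
    dm <- igraph::distances(rg$graph)
    du <- dm[upper.tri(dm)]
    expect_equal(sum(b), sum(du[is.finite(du)] - 1), tolerance = 1e-9)
  }
})

test_that("feature matrix TSV round-trips with metadata", {
  m <- suppressMessages(
    build_feature_matrix(p3, c("A", "B", "C"), c("A", "C")))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(m, f)
  m2 <- read_feature_matrix(f)
  expect_equal(as.data.frame(m2), as.data.frame(m), tolerance = 1e-12)
  expect_identical(attr(m2, "leave_one_out"), TRUE)
  expect_identical(attr(m2, "disease_checksum"), attr(m, "disease_checksum"))
})
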