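edge_df <- function(a, b, score = 900) {
  data.frame(protein1 = a, protein2 = b, combined_score = score,
             stringsAsFactors = FALSE)
}

test_that("network building filters scores, deduplicates and prunes degree", {
  # a triangle has all degrees 2, so the <=2-edge rule removes everything
  tri <- edge_df(c("A", "A", "B"), c("B", "C", "C"))
  expect_equal(length(build_ppi_network(tri)$nodes), 0)
  # K4 has degrees 3 and survives intact
  k4 <- edge_df(c("A", "A", "A", "B", "B", "C"),
                c("B", "C", "D", "C", "D", "D"))
  net <- build_ppi_network(k4)
  expect_identical(net$nodes, c("A", "B", "C", "D"))
  expect_equal(nrow(net$edges), 6)
  # below-cutoff edges and duplicates/self-loops are dropped
  messy <- rbind(k4, edge_df(c("A", "E", "B", "E"), c("E", "A", "A", "E"),
                             c(650, 800, 900, 900)))
  net2 <- build_ppi_network(messy)
  expect_false("E" %in% net2$nodes)
  expect_equal(nrow(net2$edges), 6)
  expect_error(build_ppi_network(edge_df("A", "B", 1200)),
               class = "parse_error")
})

test_that("single-pass pruning differs from iterated 3-core when it should", {
  # K4 plus a pendant chain: one pass removes the chain ends only
  e <- rbind(edge_df(c("A", "A", "A", "B", "B", "C"),
                     c("B", "C", "D", "C", "D", "D")),
             edge_df(c("D", "E", "F"), c("E", "F", "G")))
  once <- build_ppi_network(e, prune = "once")
  core <- build_ppi_network(e, prune = "kcore")
  expect_true(all(c("A", "B", "C", "D") %in% core$nodes))
  expect_false(any(c("E", "F", "G") %in% core$nodes))
  expect_true(length(once$nodes) >= length(core$nodes))
})

test_that("hand-worked centrality values are reproduced", {
  path <- build_ppi_network(edge_df(c("a", "b"), c("b", "c")),
                            min_degree_keep = 0)
  cl <- closeness_centrality(path)
  expect_equal(unname(cl[c("a", "b", "c")]), c(1.5, 2.0, 1.5))
  expect_equal(unname(mcc(path)[c("a", "b", "c")]), c(1, 2, 1))
  expect_equal(unname(mnc(path)[c("a", "b", "c")]), c(1, 1, 1))

  k4 <- build_ppi_network(edge_df(c("A", "A", "A", "B", "B", "C"),
                                  c("B", "C", "D", "C", "D", "D")))
  expect_equal(unname(mcc(k4)), rep(6, 4))           # one 4-clique, 3!
  expect_equal(unname(degree_centrality(k4)), rep(3L, 4))
  expect_equal(unname(closeness_centrality(k4)), rep(3, 4))

  tri <- build_ppi_network(edge_df(c("A", "A", "B"), c("B", "C", "C")),
                           min_degree_keep = 0)
  expect_equal(unname(mcc(tri)), rep(2, 3))
  expect_equal(unname(mnc(tri)), rep(2L, 3))

  star <- build_ppi_network(edge_df(rep("c", 4), paste0("l", 1:4)),
                            min_degree_keep = 0)
  expect_equal(unname(mnc(star)["c"]), 1L)
  expect_equal(unname(degree_centrality(star)["c"]), 4L)

  # two components: no cross-component closeness contribution
  two <- build_ppi_network(edge_df(c("A", "C"), c("B", "D")),
                           min_degree_keep = 0)
  expect_equal(unname(closeness_centrality(two)), rep(1, 4))
})

test_that("all four centralities match brute-force oracles on random graphs", {
  set.seed(101)
  for (i in 1:40) {
    e <- random_edge_list(n = sample(3:8, 1), p = runif(1, 0.2, 0.8))
    if (!nrow(e)) next
    net <- build_ppi_network(e, min_degree_keep = 0)
    A <- adj_matrix_of(net)
    expect_equal(unname(degree_centrality(net)), unname(rowSums(A)))
    expect_equal(unname(closeness_centrality(net)), closeness_oracle(A),
                 tolerance = 1e-12)
    expect_equal(unname(closeness_centrality(net, "classic")),
                 closeness_oracle(A, harmonic = FALSE), tolerance = 1e-12)
    expect_equal(unname(mcc(net)), mcc_oracle(A), tolerance = 1e-12)
    expect_equal(unname(mnc(net)), as.integer(mnc_oracle(A)))
  }
})

test_that("centralities agree with igraph where conventions coincide", {
  skip_if_not_installed("igraph")
  set.seed(202)
  e <- random_edge_list(12, 0.3)
  net <- build_ppi_network(e, min_degree_keep = 0)
  g <- igraph::graph_from_data_frame(net$edges[, 1:2], directed = FALSE)
  ord <- match(net$nodes, igraph::V(g)$name)
  expect_equal(unname(degree_centrality(net)),
               unname(igraph::degree(g)[ord]))
  expect_equal(unname(closeness_centrality(net)),
               unname(igraph::harmonic_centrality(g, normalized = FALSE)[ord]),
               tolerance = 1e-10)
  # MCC from igraph's independent maximal-clique enumerator
  cl <- igraph::max_cliques(g)
  ref <- setNames(numeric(length(net$nodes)), net$nodes)
  for (c in cl) {
    nm <- igraph::V(g)$name[c]
    ref[nm] <- ref[nm] + factorial(length(nm) - 1)
  }
  expect_equal(unname(mcc(net)), unname(ref[net$nodes]))
})

test_that("MNC never exceeds degree and 3-core pruning enforces minimum degree", {
  sim <- simulate_ppi(sim_config(seed = 31, ppi_nodes = 40,
                                 ppi_edge_prob = 0.1))
  net <- build_ppi_network(sim$edges, prune = "kcore")
  expect_gt(length(net$nodes), 0)
  expect_true(all(mnc(net) <= degree_centrality(net)))
  expect_true(all(degree_centrality(net) >= 3))
})

test_that("the MCC node cap raises a resource-limit error", {
  e <- random_edge_list(8, 0.5)
  net <- build_ppi_network(e, min_degree_keep = 0)
  expect_error(mcc(net, node_cap = 4), class = "resource_limit")
})

test_that("a planted clique dominates the MCC ranking on sparse background", {
  sim <- simulate_ppi(sim_config(seed = 21, ppi_nodes = 40,
                                 ppi_edge_prob = 0.02,
                                 planted_clique_size = 6))
  net <- build_ppi_network(sim$edges)
  cons <- top_k_consensus(centrality_table(net), k = 6)
  expect_true(all(sim$truth$clique_members %in% cons$top$mcc))
})

test_that("consensus is a deterministic intersection, invariant to order", {
  tab <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                    degree = c(3, 3, 2, 1),
                    closeness = c(2.5, 2.5, 2.0, 1.0),
                    mcc = c(6, 6, 2, 1),
                    mnc = c(3, 2, 2, 1))
  out <- top_k_consensus(tab, k = 2)
  expect_identical(out$top$degree, c("g1", "g2"))  # tie broken by symbol
  expect_identical(out$consensus, c("g1", "g2"))
  flipped <- top_k_consensus(tab, k = 2,
                             algorithms = c("closeness", "mnc", "degree", "mcc"))
  expect_identical(flipped$consensus, out$consensus)
  expect_true(all(out$consensus %in% out$top$mcc))
})

test_that("key-hub intersection reproduces set algebra", {
  expect_identical(key_hub_intersection(list(c("A", "B"), c("B", "C"))), "B")
  expect_identical(key_hub_intersection(list(c("A"), c("B"))), character(0))
  expect_identical(key_hub_intersection(list()), character(0))
})

test_that("edge lists round-trip through the TSV format", {
  sim <- simulate_ppi(sim_config(seed = 41, ppi_nodes = 15))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_edges_tsv(sim$edges, p)
  back <- read_edges_tsv(p)
  expect_equal(back$combined_score, sim$edges$combined_score)
  expect_identical(back$protein1, sim$edges$protein1)
})
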