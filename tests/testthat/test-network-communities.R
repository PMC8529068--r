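test_that("graph construction canonicalizes, sorts and rejects bad edges", {
  g <- trans_omics_graph(data.frame(from = c("b", "c"), to = c("a", "a"),
                                    rho = c(0.9, -0.4)))
  expect_identical(g$edges$from, c("a", "a"))
  expect_identical(g$edges$to, c("b", "c"))
  expect_equal(g$edges$length, 1 - abs(g$edges$rho))
  expect_error(trans_omics_graph(data.frame(from = "a", to = "a")), "self-loop")
  expect_error(trans_omics_graph(data.frame(from = c("a", "b"), to = c("b", "a"))),
               "duplicated edge")
  expect_error(trans_omics_graph(data.frame(from = "a", to = "b"),
                                 nodes = data.frame(id = "a", domain = "x")),
               "missing from nodes")
})

test_that("edge betweenness matches hand-enumerated topologies", {
  g <- two_triangle_graph()
  bc <- edge_betweenness(g)
  expect_equal(unname(bc["c|d"]), 9)  # all 3x3 cross pairs use the bridge
  expect_equal(unname(bc["a|b"]), 1)
  expect_equal(unname(bc["a|c"]), 4)  # own pair + three cross paths via c
  # 3-cycle: every pair's unique shortest path is its own edge
  tri <- trans_omics_graph(data.frame(from = c("x", "x", "y"),
                                      to = c("y", "z", "z")), edge_length = "unit")
  expect_equal(unname(edge_betweenness(tri)), rep(1, 3))
  # single edge
  one <- trans_omics_graph(data.frame(from = "u", to = "v"), edge_length = "unit")
  expect_equal(unname(edge_betweenness(one)), 1)
})

test_that("tied shortest paths share credit fractionally", {
  # 4-cycle: each pair of opposite corners has two tied 2-step paths
  g <- trans_omics_graph(data.frame(from = c("a", "b", "c", "a"),
                                    to = c("b", "c", "d", "d")),
                         edge_length = "unit")
  bc <- edge_betweenness(g)
  # every edge: its endpoint pair (1) + half credit from both diagonals
  expect_equal(unname(bc), rep(2, 4))
})

test_that("edge betweenness equals exhaustive path enumeration on random graphs", {
  skip_if_not_installed("igraph")
  for (s in 1:20) {
    g <- random_unit_graph(n_nodes = sample(4:10, 1), p_edge = 0.4, seed = s)
    expect_equal(edge_betweenness(g), enumeration_edge_betweenness(g),
                 tolerance = 1e-9)
  }
})

test_that("weighted betweenness routes along strong-correlation short paths", {
  # a--b--c chain with strong rho plus a weak direct a--c edge: the two-step
  # strong path (length 0.2) beats the direct weak edge (length 0.8)
  g <- trans_omics_graph(data.frame(from = c("a", "b", "a"),
                                    to = c("b", "c", "c"),
                                    rho = c(0.9, 0.9, 0.2)))
  bc <- edge_betweenness(g)
  expect_equal(unname(bc["a|b"]), 2)  # pairs ab and ac
  expect_equal(unname(bc["b|c"]), 2)
  expect_equal(unname(bc["a|c"]), 0)
  skip_if_not_installed("igraph")
  ig <- igraph::graph_from_data_frame(g$edges[, c("from", "to")], directed = FALSE)
  ref <- igraph::edge_betweenness(ig, weights = g$edges$length)
  expect_equal(unname(bc), ref)
})

test_that("betweenness sums to total pairwise path length on trees", {
  skip_if_not_installed("igraph")
  set.seed(40)
  for (i in 1:10) {
    n <- sample(5:12, 1)
    parent <- c(NA, vapply(2:n, function(k) sample(k - 1, 1), integer(1)))
    ids <- sprintf("t%02d", 1:n)
    g <- trans_omics_graph(data.frame(from = ids[parent[-1]], to = ids[-1]),
                           edge_length = "unit")
    ig <- igraph::graph_from_data_frame(g$edges[, c("from", "to")], directed = FALSE)
    total_len <- sum(igraph::distances(ig)[upper.tri(diag(n))])
    expect_equal(sum(edge_betweenness(g)), total_len)
  }
})

test_that("modularity matches hand formulas", {
  g <- two_triangle_graph()
  both <- setNames(c(1, 1, 1, 2, 2, 2), c("a", "b", "c", "d", "e", "f"))
  expect_equal(modularity_q(g, both), 5 / 14, tolerance = 1e-12)
  one <- setNames(rep(1, 6), names(both))
  expect_equal(modularity_q(g, one), 0)
  # singleton partition of a clique is negative: Q = -sum (d_c/2m)^2
  k4 <- trans_omics_graph(data.frame(from = c("a", "a", "a", "b", "b", "c"),
                                     to = c("b", "c", "d", "c", "d", "d")),
                          edge_length = "unit")
  singles <- setNames(1:4, c("a", "b", "c", "d"))
  expect_equal(modularity_q(k4, singles), -4 * (3 / 12)^2, tolerance = 1e-12)
  skip_if_not_installed("igraph")
  set.seed(41)
  for (i in 1:5) {
    g2 <- random_unit_graph(8, 0.5, seed = 100 + i)
    memb <- sample(1:3, 8, replace = TRUE)
    ig <- igraph::graph_from_data_frame(g2$edges[, c("from", "to")],
                                        directed = FALSE, vertices = g2$nodes$id)
    expect_equal(modularity_q(g2, setNames(memb, g2$nodes$id)),
                 igraph::modularity(ig, memb), tolerance = 1e-12)
  }
})

test_that("Girvan-Newman splits the two-triangle graph at the bridge", {
  g <- two_triangle_graph()
  gn <- girvan_newman(g)
  expect_identical(gn$removal_order[1], "c|d")
  expect_equal(gn$n_communities, 2L)
  expect_equal(gn$modularity, 5 / 14, tolerance = 1e-12)
  expect_equal(length(unique(gn$membership[c("a", "b", "c")])), 1L)
  expect_equal(length(unique(gn$membership[c("d", "e", "f")])), 1L)
  # brute force over all 2^6 bipartitions confirms 5/14 is the maximum
  best <- max(vapply(0:63, function(mask) {
    memb <- setNames(as.integer(intToBits(mask))[1:6], names(gn$membership))
    modularity_q(g, memb)
  }, numeric(1)))
  expect_equal(gn$modularity, best, tolerance = 1e-12)
})

test_that("Girvan-Newman is deterministic and handles edgeless graphs", {
  g <- two_triangle_graph()
  expect_identical(girvan_newman(g)$removal_order, girvan_newman(g)$removal_order)
  lone <- trans_omics_graph(data.frame(from = "a", to = "b")[0, ],
                            nodes = data.frame(id = c("a", "b", "c"),
                                               domain = "x"))
  gn0 <- girvan_newman(lone)
  expect_equal(gn0$n_communities, 3L)
  expect_equal(gn0$modularity, 0)
  # selected partition never does worse than the trivial one-community cut
  set.seed(42)
  for (i in 1:5) {
    gr <- random_unit_graph(10, 0.3, seed = 200 + i)
    expect_gte(girvan_newman(gr)$modularity,
               modularity_q(gr, setNames(rep(1, 10), gr$nodes$id)))
  }
})

test_that("Girvan-Newman recovers planted two-block graphs", {
  ok <- vapply(1:30, function(s) {
    pb <- planted_block_graph(seed = s)
    gn <- girvan_newman(pb$graph)
    if (gn$n_communities != 2L) return(FALSE)
    m <- gn$membership[names(pb$block)]
    all(tapply(m, pb$block, function(x) length(unique(x)) == 1L))
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("community summary reproduces the worked percentage arithmetic", {
  # triangular community: 14 + 181 + 75 = 270 edges -> 5% / 67% / 28%
  g <- domain_count_graph(41, 53, 23, n_mgs_phe = 14, n_met_phe = 181,
                          n_mgs_met = 75)
  memb <- setNames(rep(1, nrow(g$nodes)), g$nodes$id)
  cs <- community_summary(g, memb, min_size = 5)
  e <- cs$edges
  expect_equal(e$n_edges[e$domain_pair == "MGS--phenotype"], 14)
  expect_equal(e$percent_display[e$domain_pair == "MGS--phenotype"], 5)
  expect_equal(e$percent_display[e$domain_pair == "metabolite--phenotype"], 67)
  expect_equal(e$percent_display[e$domain_pair == "MGS--metabolite"], 28)
  expect_equal(sum(e$percent), 100, tolerance = 1e-9)

  # dense microbe-metabolite community: 1040 of 1049 edges -> 99.1%
  g2 <- domain_count_graph(200, 33, 5, n_mgs_phe = 3, n_met_phe = 6,
                           n_mgs_met = 1040)
  memb2 <- setNames(rep(1, nrow(g2$nodes)), g2$nodes$id)
  e2 <- community_summary(g2, memb2, min_size = 5)$edges
  expect_equal(e2$n_edges[e2$domain_pair == "MGS--metabolite"], 1040)
  expect_equal(e2$percent_display[e2$domain_pair == "MGS--metabolite"], 99.1)
  expect_equal(sum(e2$percent), 100, tolerance = 1e-9)
})

test_that("community summary prunes small communities and counts edge signs", {
  g <- trans_omics_graph(
    data.frame(from = c("a", "a", "b", "c", "d", "x"),
               to = c("b", "c", "c", "d", "e", "y"),
               rho = c(0.5, 0.6, -0.4, 0.7, 0.5, 0.9)),
    nodes = data.frame(id = c("a", "b", "c", "d", "e", "x", "y"),
                       domain = c("MGS", "metabolite", "MGS", "metabolite",
                                  "MGS", "MGS", "metabolite")))
  memb <- setNames(c(1, 1, 1, 1, 1, 2, 2), c("a", "b", "c", "d", "e", "x", "y"))
  cs <- community_summary(g, memb, min_size = 5)
  expect_equal(nrow(cs$communities), 1L)  # the 2-node community is pruned
  expect_equal(cs$communities$n_nodes, 5)
  expect_equal(sum(cs$edges$n_negative), 1)
  expect_equal(sum(cs$edges$n_positive), 4)
  empty <- community_summary(g, memb, min_size = 50)
  expect_equal(nrow(empty$communities), 0L)
})

test_that("graphml export is well-formed xml with all nodes and edges", {
  skip_if_not_installed("igraph")
  g <- two_triangle_graph()
  path <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g, path, girvan_newman(g)$membership)
  ig <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(ig), 6)
  expect_equal(igraph::ecount(ig), 7)
})
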