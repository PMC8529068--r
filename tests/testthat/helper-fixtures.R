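# Shared fixtures, all built in code.

# toy samples x features omics matrix with reproducible values
toy_matrix <- function(n = 6, p = 4, domain = "metabolite", seed = 1,
                       positive = TRUE) {
  set.seed(seed)
  v <- matrix(rnorm(n * p), n, p)
  if (positive) v <- exp(v)
  dimnames(v) <- list(sprintf("S%02d", seq_len(n)), sprintf("F%02d", seq_len(p)))
  omics_matrix(v, domain)
}

# two 3-cliques joined by one bridge (c--d), unit edge lengths
two_triangle_graph <- function() {
  trans_omics_graph(
    data.frame(from = c("a", "a", "b", "c", "d", "d", "e"),
               to   = c("b", "c", "c", "d", "e", "f", "f")),
    edge_length = "unit")
}

# Erdos-Renyi graph with unit lengths; guaranteed non-empty edge set
random_unit_graph <- function(n_nodes, p_edge, seed) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- t(combn(ids, 2))
  keep <- runif(nrow(pairs)) < p_edge
  if (!any(keep)) keep[sample(nrow(pairs), 1)] <- TRUE
  trans_omics_graph(data.frame(from = pairs[keep, 1], to = pairs[keep, 2]),
                    nodes = data.frame(id = ids, domain = "unknown"),
                    edge_length = "unit")
}

# exhaustive shortest-path enumeration oracle for edge betweenness, built on
# igraph's path enumeration (independent of the Brandes implementation)
enumeration_edge_betweenness <- function(graph) {
  ig <- igraph::graph_from_data_frame(graph$edges[, c("from", "to")],
                                      directed = FALSE,
                                      vertices = graph$nodes$id)
  bc <- setNames(numeric(nrow(graph$edges)), graph$edges$id)
  ids <- graph$nodes$id
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      sp <- suppressWarnings( # unreachable pairs warn on disconnected graphs
        igraph::all_shortest_paths(ig, from = ids[i], to = ids[j],
                                   weights = graph$edges$length))$vpaths
      if (length(sp) == 0) next
      for (path in sp) {
        nm <- igraph::V(ig)$name[as.integer(path)]
        if (length(nm) < 2) next
        for (k in seq_len(length(nm) - 1)) {
          e <- paste(sort(nm[k:(k + 1)]), collapse = "|")
          bc[e] <- bc[e] + 1 / length(sp)
        }
      }
    }
  }
  bc
}

# planted two-block graph for community recovery checks
planted_block_graph <- function(n_per_block = 10, p_in = 0.9, p_out = 0.05,
                                seed = 1) {
  set.seed(seed)
  ids <- c(sprintf("a%02d", seq_len(n_per_block)),
           sprintf("b%02d", seq_len(n_per_block)))
  block <- rep(1:2, each = n_per_block)
  pairs <- t(combn(seq_along(ids), 2))
  pr <- ifelse(block[pairs[, 1]] == block[pairs[, 2]], p_in, p_out)
  keep <- runif(nrow(pairs)) < pr
  list(graph = trans_omics_graph(
         data.frame(from = ids[pairs[keep, 1]], to = ids[pairs[keep, 2]]),
         nodes = data.frame(id = ids, domain = "unknown"),
         edge_length = "unit"),
       block = setNames(block, ids))
}

# single-community graph fixture with exact per-domain-pair edge counts;
# edges are enumerated deterministically and a spanning chain keeps the
# graph connected within one community
domain_count_graph <- function(n_mgs, n_met, n_phe,
                               n_mgs_phe, n_met_phe, n_mgs_met) {
  mgs <- sprintf("MGS%03d", seq_len(n_mgs))
  met <- sprintf("ME%03d", seq_len(n_met))
  phe <- sprintf("PHE%03d", seq_len(n_phe))
  pick <- function(a, b, k) {
    pairs <- expand.grid(a = a, b = b, stringsAsFactors = FALSE)
    stopifnot(nrow(pairs) >= k)
    pairs[seq_len(k), ]
  }
  p1 <- pick(mgs, phe, n_mgs_phe)
  p2 <- pick(met, phe, n_met_phe)
  p3 <- pick(mgs, met, n_mgs_met)
  edges <- data.frame(from = c(p1$a, p2$a, p3$a), to = c(p1$b, p2$b, p3$b),
                      rho = 0.5, stringsAsFactors = FALSE)
  nodes <- data.frame(id = c(mgs, met, phe),
                      domain = rep(c("MGS", "metabolite", "phenotype"),
                                   c(n_mgs, n_met, n_phe)))
  used <- unique(c(edges$from, edges$to))
  nodes <- nodes[nodes$id %in% used, ]
  trans_omics_graph(edges, nodes = nodes, edge_length = "unit")
}
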