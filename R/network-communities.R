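#' Node-typed undirected trans-omics graph
#'
#' Container for the filtered inter-omic correlation network. Edges are
#' canonicalized (`from < to` lexicographically), deduplicated, sorted, and
#' given a shortest-path length: by default `1 - |rho|` (stronger
#' correlation = shorter path, floored at 1e-6), or unit lengths.
#'
#' @param edges data.frame with columns `from`, `to` and optionally `rho`
#'   (defaults to 1, i.e. unit strength).
#' @param nodes optional data.frame with columns `id`, `domain`; inferred
#'   from the edges (domain `"unknown"`) when omitted.
#' @param edge_length `"correlation"` for `1 - |rho|` lengths or `"unit"`.
#' @return object of class `trans_omics_graph`: list with `nodes` and
#'   `edges` data.frames (edges carry `from`, `to`, `rho`, `length`, `id`).
#' @export
trans_omics_graph <- function(edges, nodes = NULL,
                              edge_length = c("correlation", "unit")) {
  edge_length <- match.arg(edge_length)
  stopifnot(all(c("from", "to") %in% names(edges)))
  if (is.null(edges$rho)) edges$rho <- rep(1, nrow(edges))
  if (any(edges$from == edges$to)) stop("self-loops are not allowed")
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]; edges$to[swap] <- tmp
  edges$id <- paste(edges$from, edges$to, sep = "|")
  if (anyDuplicated(edges$id))
    stop("duplicated edge(s): ", paste(head(edges$id[duplicated(edges$id)], 5), collapse = ", "))
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  if (is.null(nodes)) {
    ids <- sort(unique(c(edges$from, edges$to)))
    nodes <- data.frame(id = ids, domain = "unknown", stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("id", "domain") %in% names(nodes)))
    if (anyDuplicated(nodes$id)) stop("duplicated node ids")
    missing <- setdiff(c(edges$from, edges$to), nodes$id)
    if (length(missing) > 0L)
      stop("edge endpoint(s) missing from nodes: ", paste(head(missing, 5), collapse = ", "))
    nodes <- nodes[order(nodes$id), , drop = FALSE]
    rownames(nodes) <- NULL
  }
  edges$length <- if (edge_length == "unit") rep(1, nrow(edges)) else
    pmax(1 - abs(edges$rho), 1e-6)
  structure(list(nodes = nodes,
                 edges = edges[, c("from", "to", "rho", "length", "id")]),
            class = "trans_omics_graph")
}

#' Build the trans-omics graph from a filtered edge set
#'
#' @param edge_set data.frame from [filter_for_network()] (columns
#'   `feature_a`, `domain_a`, `feature_b`, `domain_b`, `rho`).
#' @inheritParams trans_omics_graph
#' @return a [trans_omics_graph()].
#' @export
graph_from_edges <- function(edge_set, edge_length = c("correlation", "unit")) {
  nodes <- unique(rbind(
    data.frame(id = edge_set$feature_a, domain = edge_set$domain_a),
    data.frame(id = edge_set$feature_b, domain = edge_set$domain_b)))
  trans_omics_graph(
    data.frame(from = edge_set$feature_a, to = edge_set$feature_b,
               rho = edge_set$rho, stringsAsFactors = FALSE),
    nodes = nodes, edge_length = match.arg(edge_length))
}

#' @export
print.trans_omics_graph <- function(x, ...) {
  cat(sprintf("<trans_omics_graph> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

# component membership (1-based consecutive labels) by union-find
.components <- function(n_nodes, ef, et) {
  parent <- seq_len(n_nodes)
  for (k in seq_along(ef)) {
    i <- ef[k]
    while (parent[i] != i) { parent[i] <- parent[parent[i]]; i <- parent[i] }
    j <- et[k]
    while (parent[j] != j) { parent[j] <- parent[parent[j]]; j <- parent[j] }
    if (i != j) parent[j] <- i
  }
  for (v in seq_len(n_nodes)) {
    i <- v
    while (parent[i] != i) i <- parent[i]
    parent[v] <- i
  }
  match(parent, unique(parent))
}

.edge_index <- function(graph) {
  list(from = match(graph$edges$from, graph$nodes$id),
       to = match(graph$edges$to, graph$nodes$id))
}

#' Weighted edge betweenness centrality
#'
#' For every edge, the number of shortest paths (by edge length) between all
#' unordered node pairs that pass over it, with fractional credit shared
#' among tied shortest paths. Disconnected graphs are handled per component.
#'
#' @param graph a [trans_omics_graph()].
#' @return named numeric vector (edge id -> betweenness).
#' @export
edge_betweenness <- function(graph) {
  stopifnot(inherits(graph, "trans_omics_graph"))
  if (nrow(graph$edges) == 0L) return(setNames(numeric(0), character(0)))
  idx <- .edge_index(graph)
  bc <- brandes_edge_betweenness(nrow(graph$nodes), idx$from - 1L, idx$to - 1L,
                                 graph$edges$length)
  setNames(bc, graph$edges$id)
}

#' Newman-Girvan modularity of a partition
#'
#' `Q = sum_c (e_c / m - (d_c / 2m)^2)` on unweighted edge counts, where
#' `e_c` is the number of edges inside community `c`, `d_c` the total degree
#' of its nodes and `m` the edge count. `Q = 0` for an edgeless graph and
#' for the all-in-one partition.
#'
#' @param graph a [trans_omics_graph()].
#' @param membership named vector node id -> community label, covering all
#'   nodes (or unnamed in `graph$nodes$id` order).
#' @return modularity Q in `[-0.5, 1]`.
#' @export
modularity_q <- function(graph, membership) {
  m <- nrow(graph$edges)
  if (m == 0L) return(0)
  memb <- if (is.null(names(membership))) membership else membership[graph$nodes$id]
  if (anyNA(memb)) stop("membership must cover all nodes")
  idx <- .edge_index(graph)
  within <- memb[idx$from] == memb[idx$to]
  e_c <- tapply(within, memb[idx$from], sum)
  deg <- tabulate(c(idx$from, idx$to), nbins = nrow(graph$nodes))
  d_c <- tapply(deg, memb, sum)
  comms <- unique(as.character(memb))
  e_by <- setNames(rep(0, length(comms)), comms)
  e_by[names(e_c)] <- e_c
  sum(e_by / m - (d_c[comms] / (2 * m))^2)
}

#' Girvan-Newman community decomposition
#'
#' Iteratively removes the edge of maximal betweenness (recomputed after
#' every removal; ties broken deterministically by lexicographic edge id),
#' recording the connected-component partition each time a split occurs,
#' until no edges remain. The returned partition is the recorded one (the
#' initial components included) that maximizes Newman-Girvan modularity on
#' the original graph; the earliest cut wins ties.
#'
#' @param graph a [trans_omics_graph()].
#' @return object of class `community_partition`: list with `membership`
#'   (named integer vector node -> community), `modularity` (Q of the
#'   selected cut), `n_communities`, and `removal_order` (edge ids).
#' @export
girvan_newman <- function(graph) {
  stopifnot(inherits(graph, "trans_omics_graph"))
  n <- nrow(graph$nodes)
  idx <- .edge_index(graph)
  active <- rep(TRUE, nrow(graph$edges))
  memb <- .components(n, idx$from, idx$to)
  partitions <- list(memb)
  ncomp <- max(memb)
  removal <- character(0)
  while (any(active)) {
    sub <- which(active)
    bc <- brandes_edge_betweenness(n, idx$from[sub] - 1L, idx$to[sub] - 1L,
                                   graph$edges$length[sub])
    drop <- sub[which.max(bc)] # edges pre-sorted: first max = lexicographic tie rule
    active[drop] <- FALSE
    removal <- c(removal, graph$edges$id[drop])
    memb <- .components(n, idx$from[active], idx$to[active])
    if (max(memb) > ncomp) {
      partitions[[length(partitions) + 1L]] <- memb
      ncomp <- max(memb)
    }
  }
  qs <- vapply(partitions, function(p) modularity_q(graph, setNames(p, graph$nodes$id)),
               numeric(1))
  best <- partitions[[which.max(qs)]]
  structure(list(membership = setNames(best, graph$nodes$id),
                 modularity = max(qs),
                 n_communities = max(best),
                 removal_order = removal),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %d communities, Q = %.4f\n",
              x$n_communities, x$modularity))
  invisible(x)
}

#' Summarize communities by domain composition
#'
#' For every community of at least `min_size` nodes ("pruning the loose
#' connections"), tabulates node counts per domain and edge counts and
#' percentages per domain pair, plus positive/negative edge counts by the
#' sign of rho. Percentages are of that community's own edge total and are
#' displayed to one decimal when the community has >= 1000 edges, to the
#' nearest integer otherwise; the raw percentages always sum to 100.
#'
#' @param graph a [trans_omics_graph()].
#' @param membership named vector node id -> community (e.g. from
#'   [girvan_newman()]).
#' @param min_size minimum community node count retained.
#' @return list with `communities` (data.frame `community`, `n_nodes`,
#'   `n_edges` plus one `nodes_<domain>` column per domain) and `edges`
#'   (data.frame `community`, `domain_pair`, `n_edges`, `percent`,
#'   `percent_display`, `n_positive`, `n_negative`).
#' @export
community_summary <- function(graph, membership, min_size = 5) {
  memb <- if (is.null(names(membership))) setNames(membership, graph$nodes$id) else membership
  sizes <- table(memb)
  keep <- names(sizes)[sizes >= min_size]
  keep <- keep[order(-sizes[keep])]
  if (length(keep) == 0L)
    return(list(communities = data.frame(), edges = data.frame()))
  dom <- setNames(graph$nodes$domain, graph$nodes$id)
  ef <- memb[graph$edges$from]; et <- memb[graph$edges$to]
  comm_rows <- list(); edge_rows <- list()
  for (cm in keep) {
    members <- names(memb)[memb == cm]
    in_edges <- graph$edges[ef == cm & et == cm, , drop = FALSE]
    ndom <- table(factor(dom[members], levels = sort(unique(dom))))
    row <- data.frame(community = cm, n_nodes = length(members),
                      n_edges = nrow(in_edges))
    for (d in names(ndom)) row[[paste0("nodes_", d)]] <- as.integer(ndom[[d]])
    comm_rows[[cm]] <- row
    if (nrow(in_edges) > 0L) {
      pair <- apply(cbind(dom[in_edges$from], dom[in_edges$to]), 1L,
                    function(x) paste(sort(x), collapse = "--"))
      tot <- nrow(in_edges)
      digits <- if (tot >= 1000L) 1L else 0L
      for (pp in sort(unique(pair))) {
        sel <- pair == pp
        pct <- 100 * sum(sel) / tot
        edge_rows[[paste(cm, pp)]] <- data.frame(
          community = cm, domain_pair = pp, n_edges = sum(sel),
          percent = pct, percent_display = round(pct, digits),
          n_positive = sum(in_edges$rho[sel] > 0),
          n_negative = sum(in_edges$rho[sel] < 0))
      }
    }
  }
  list(communities = do.call(rbind, c(comm_rows, list(make.row.names = FALSE))),
       edges = do.call(rbind, c(edge_rows, list(make.row.names = FALSE))))
}

#' Export a trans-omics graph with its communities as GraphML
#'
#' Minimal GraphML writer (node domain, community, edge rho) for use in
#' external viewers.
#'
#' @param graph a [trans_omics_graph()].
#' @param membership optional community membership to attach to nodes.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path, membership = NULL) {
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", gsub(">", "&gt;", x)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="domain" for="node" attr.name="domain" attr.type="string"/>',
    '  <key id="community" for="node" attr.name="community" attr.type="string"/>',
    '  <key id="rho" for="edge" attr.name="rho" attr.type="double"/>',
    '  <graph edgedefault="undirected">'), con)
  for (i in seq_len(nrow(graph$nodes))) {
    id <- graph$nodes$id[i]
    cm <- if (is.null(membership)) "" else as.character(membership[[id]])
    writeLines(sprintf('    <node id="%s"><data key="domain">%s</data><data key="community">%s</data></node>',
                       esc(id), esc(graph$nodes$domain[i]), esc(cm)), con)
  }
  for (i in seq_len(nrow(graph$edges)))
    writeLines(sprintf('    <edge source="%s" target="%s"><data key="rho">%.10g</data></edge>',
                       esc(graph$edges$from[i]), esc(graph$edges$to[i]),
                       graph$edges$rho[i]), con)
  writeLines(c('  </graph>', '</graphml>'), con)
  invisible(path)
}
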