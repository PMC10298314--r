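#' Build the pathway network from flagged pairs
#'
#' Each significant pathway pair becomes an undirected edge between its two
#' pathways; duplicate pairs collapse, and the node set is the union of
#' endpoints. The result is a simple igraph graph.
#'
#' @param flagged_pairs Character vector of "idA-idB" pair ids.
#' @return An igraph undirected simple graph (possibly empty).
#' @export
build_graph <- function(flagged_pairs) {
  flagged_pairs <- as.character(flagged_pairs)
  if (length(flagged_pairs) == 0L) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  parts <- strsplit(flagged_pairs, "-", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) stop("malformed pair id: ", flagged_pairs[bad][1L])
  ends <- t(vapply(parts, identity, character(2L)))
  g <- igraph::graph_from_edgelist(ends, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Rank nodes by Maximal Clique Centrality
#'
#' MCC(v) is the sum over all maximal cliques C containing v of (|C| - 1)!,
#' the hub statistic of cytoHubba. Maximal cliques are enumerated exactly
#' (Bron-Kerbosch, via igraph); a node incident to no edge scores 0, and a
#' degree-d node in a triangle-free graph scores exactly d (each incident
#' edge is a maximal 2-clique). Ties share a score and are ordered by node
#' name for determinism.
#'
#' @param graph An undirected simple igraph graph.
#' @return Data frame with `node` and `mcc`, sorted by decreasing score then
#'   node name.
#' @export
mcc_rank <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0L) return(data.frame(node = character(0), mcc = numeric(0)))
  nodes <- igraph::V(graph)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  score <- stats::setNames(numeric(n), nodes)
  cliques <- igraph::max_cliques(graph, min = 2L)
  for (cl in cliques) {
    w <- factorial(length(cl) - 1L)
    members <- nodes[as.integer(cl)]
    score[members] <- score[members] + w
  }
  out <- data.frame(node = nodes, mcc = unname(score))
  out[order(-out$mcc, out$node), , drop = FALSE]
}

#' Hub subnetwork: top-ranked pathways plus their neighbors
#'
#' Induced subgraph on the `top_n` highest-MCC nodes together with all their
#' first neighbors, the construction used to display the core pathway
#' network.
#'
#' @param graph An undirected simple igraph graph.
#' @param ranking Data frame from [mcc_rank()] (recomputed if NULL).
#' @param top_n Number of hub nodes to keep (default 10).
#' @return The induced igraph subgraph.
#' @export
hub_subnetwork <- function(graph, ranking = NULL, top_n = 10L) {
  stopifnot(top_n >= 1L)
  if (is.null(ranking)) ranking <- mcc_rank(graph)
  if (top_n > nrow(ranking)) {
    warning("top_n exceeds node count; returning the whole graph")
    return(graph)
  }
  hubs <- ranking$node[seq_len(top_n)]
  nbrs <- unique(unlist(lapply(hubs, function(v) {
    igraph::V(graph)$name[as.integer(igraph::neighbors(graph, v))]
  })))
  igraph::induced_subgraph(graph, union(hubs, nbrs))
}
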