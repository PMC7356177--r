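# Undirected simple interaction network with per-edge evidence scores.
# Stored as a node vector plus a canonical edge tibble (from < to, sorted),
# so identical graphs always have identical representations regardless of
# input order.

empty_edges <- function() {
  tibble(from = character(0), to = character(0), score = numeric(0))
}

#' Construct an interaction network
#'
#' Builds an undirected simple graph from an edge tibble. Self-loops are
#' dropped; duplicate and reciprocal edges collapse keeping the maximum
#' score; edges below `min_score` are excluded. Nodes not named in `nodes`
#' are taken from the edges.
#'
#' @param edges Tibble with columns `from`, `to`, `score`.
#' @param nodes Optional character vector of node names (allows isolated
#'   nodes).
#' @param min_score Minimum score for an edge to be kept (default 0: keep
#'   all).
#' @return An object of class `ppi_network` with elements `nodes` (sorted
#'   character vector) and `edges` (canonical tibble).
#' @export
ppi_network <- function(edges = empty_edges(), nodes = character(0),
                        min_score = 0) {
  edges <- as_tibble(edges)
  stopifnot(all(c("from", "to", "score") %in% names(edges)))
  edges <- edges |>
    mutate(from = as.character(.data$from), to = as.character(.data$to),
           score = as.numeric(.data$score)) |>
    filter(.data$from != .data$to)
  if (nrow(edges) > 0) {
    # canonicalize endpoint order via radix ranks (locale-independent)
    u <- sort_c(unique(c(edges$from, edges$to)))
    ia <- match(edges$from, u)
    ib <- match(edges$to, u)
    a <- ifelse(ia <= ib, edges$from, edges$to)
    b <- ifelse(ia <= ib, edges$to, edges$from)
    edges <- tibble(from = a, to = b, score = edges$score) |>
      group_by(.data$from, .data$to) |>
      summarise(score = max(.data$score), .groups = "drop") |>
      filter(.data$score >= min_score) |>
      arrange(.data$from, .data$to)
  }
  nodes <- sort_c(unique(c(as.character(nodes), edges$from, edges$to)))
  structure(list(nodes = nodes, edges = edges), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' @method as_tibble ppi_network
#' @export
as_tibble.ppi_network <- function(x, ...) x$edges

# named list: node -> character vector of neighbors
adjacency_list <- function(network) {
  adj <- setNames(vector("list", length(network$nodes)), network$nodes)
  for (nm in network$nodes) adj[[nm]] <- character(0)
  if (nrow(network$edges) > 0) {
    sp1 <- split(network$edges$to, network$edges$from)
    sp2 <- split(network$edges$from, network$edges$to)
    for (nm in names(sp1)) adj[[nm]] <- c(adj[[nm]], sp1[[nm]])
    for (nm in names(sp2)) adj[[nm]] <- c(adj[[nm]], sp2[[nm]])
  }
  adj
}

node_degrees <- function(network) {
  deg <- setNames(integer(length(network$nodes)), network$nodes)
  if (nrow(network$edges) > 0) {
    t1 <- table(network$edges$from)
    t2 <- table(network$edges$to)
    deg[names(t1)] <- deg[names(t1)] + as.integer(t1)
    deg[names(t2)] <- deg[names(t2)] + as.integer(t2)
  }
  deg
}

# induced subgraph on a node subset (keeps isolated members as nodes)
induce_subgraph <- function(network, members) {
  members <- intersect(network$nodes, members)
  keep <- network$edges$from %in% members & network$edges$to %in% members
  ppi_network(edges = network$edges[keep, , drop = FALSE], nodes = members)
}

#' Induce the DEG interaction network
#'
#' Subgraph of the full interaction network induced on the differentially
#' expressed genes. Genes absent from the network are ignored; an empty
#' intersection yields an empty graph.
#'
#' @param network A [ppi_network()].
#' @param degs Character vector of DEG identifiers.
#' @return A [ppi_network()].
#' @export
induce_deg_network <- function(network, degs) {
  stopifnot(inherits(network, "ppi_network"))
  induce_subgraph(network, unique(as.character(degs)))
}

#' Count functionally connected genes
#'
#' Number of network nodes with degree >= 1.
#'
#' @param network A [ppi_network()].
#' @return Integer count.
#' @export
count_connected <- function(network) {
  stopifnot(inherits(network, "ppi_network"))
  sum(node_degrees(network) >= 1L)
}

#' Graph density
#'
#' `2m / (n (n - 1))` for a simple undirected graph with `n` nodes and `m`
#' edges; defined as 0 when `n < 2`.
#'
#' @param network A [ppi_network()].
#' @return Real in `[0, 1]`.
#' @export
graph_density <- function(network) {
  n <- length(network$nodes)
  if (n < 2) return(0)
  2 * nrow(network$edges) / (n * (n - 1))
}

#' k-core of a network by iterative peeling
#'
#' The maximal subgraph in which every node has degree >= `k` within the
#' subgraph, obtained by repeatedly deleting nodes of degree < `k`. Returns
#' an empty graph when no such subgraph exists.
#'
#' @param network A [ppi_network()].
#' @param k Positive integer.
#' @return A [ppi_network()].
#' @export
k_core <- function(network, k) {
  stopifnot(inherits(network, "ppi_network"), k >= 1)
  g <- network
  repeat {
    deg <- node_degrees(g)
    drop <- names(deg)[deg < k]
    if (length(drop) == 0) break
    g <- induce_subgraph(g, setdiff(g$nodes, drop))
    if (length(g$nodes) == 0) break
  }
  g
}

# highest k such that the k-core is non-empty, plus that core; k_max = 0 for
# edgeless graphs (core = the graph itself by convention, density 0)
highest_core <- function(network) {
  if (nrow(network$edges) == 0) {
    return(list(k = 0L, core = network))
  }
  k <- 1L
  core <- network
  repeat {
    nxt <- k_core(core, k + 1L)
    if (length(nxt$nodes) == 0) break
    k <- k + 1L
    core <- nxt
  }
  list(k = k, core = k_core(core, k))
}

#' MCODE-style vertex weights
#'
#' For each node, take the subgraph induced on its closed neighborhood, find
#' the highest k-core of that subgraph, and set
#' `weight = k * density(core)`. Isolated nodes get weight 0.
#'
#' @param network A [ppi_network()].
#' @return Named numeric vector of weights, one per node.
#' @export
vertex_weights <- function(network) {
  stopifnot(inherits(network, "ppi_network"))
  adj <- adjacency_list(network)
  w <- setNames(numeric(length(network$nodes)), network$nodes)
  for (v in network$nodes) {
    nb <- adj[[v]]
    if (length(nb) == 0) next
    sub <- induce_subgraph(network, c(v, nb))
    hc <- highest_core(sub)
    w[[v]] <- hc$k * graph_density(hc$core)
  }
  w
}
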