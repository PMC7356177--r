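# Dense-module detection: seeded greedy growth over MCODE-style vertex
# weights, followed by haircut, a triangle-coherence split, and a k-core
# post-filter. Fully deterministic given the documented tie-breaks.

# iterated haircut: drop members of within-candidate degree < 2 until stable
haircut_members <- function(network, members) {
  repeat {
    sub <- induce_subgraph(network, members)
    deg <- node_degrees(sub)
    drop <- names(deg)[deg < 2L]
    if (length(drop) == 0 || length(sub$nodes) == 0) break
    members <- setdiff(members, drop)
  }
  intersect(members, network$nodes)
}

# coherence: remove candidate edges that close no triangle within the
# candidate, then split into connected components. A bridge joining two
# dense regions has no triangle support and is severed; edges inside a dense
# region always do (two nodes of a near-clique share neighbors).
coherent_components <- function(network, members) {
  sub <- induce_subgraph(network, members)
  if (nrow(sub$edges) == 0) {
    return(map(sub$nodes, ~.x))
  }
  adj <- adjacency_list(sub)
  supported <- map_lgl(seq_len(nrow(sub$edges)), function(i) {
    length(intersect(adj[[sub$edges$from[i]]], adj[[sub$edges$to[i]]])) > 0
  })
  kept <- ppi_network(edges = sub$edges[supported, , drop = FALSE],
                      nodes = sub$nodes)
  connected_components(kept)
}

connected_components <- function(network) {
  adj <- adjacency_list(network)
  seen <- setNames(logical(length(network$nodes)), network$nodes)
  comps <- list()
  for (v in network$nodes) {
    if (seen[[v]]) next
    comp <- character(0)
    queue <- v
    seen[[v]] <- TRUE
    while (length(queue) > 0) {
      u <- queue[[1]]
      queue <- queue[-1]
      comp <- c(comp, u)
      for (w in adj[[u]]) {
        if (!seen[[w]]) {
          seen[[w]] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort_c(comp)
  }
  comps
}

#' Detect dense gene modules
#'
#' MCODE-style seeded clustering. Nodes are weighted by the density of the
#' highest k-core of their closed neighborhood ([vertex_weights()]). The
#' highest-weight unused node seeds a candidate, which grows breadth-first
#' through neighbors whose weight exceeds `seed_weight * (1 -
#' node_score_cutoff)` (strict inequality); every included node is marked
#' used, so modules are node-disjoint. Candidates are post-processed:
#' `haircut` iteratively removes members with within-candidate degree < 2; a
#' coherence step severs candidate edges that close no triangle inside the
#' candidate and splits the candidate into connected components (so a single
#' bridge edge cannot fuse two dense regions); components that do not contain
#' a non-empty k-core at `k_core_filter` are discarded. Surviving modules are
#' scored `density * size` and labeled `M1, M2, ...` in descending score
#' (ties: larger size, then lexicographically smallest member).
#'
#' @param network A [ppi_network()].
#' @param k_core_filter Each reported module must contain a non-empty k-core
#'   at this k (default 4).
#' @param node_score_cutoff Expansion threshold in `[0, 1)` (default 0.2).
#' @param haircut Remove weakly attached members (default `TRUE`).
#' @param fluff Re-attach neighborhood nodes after haircut (default `FALSE`;
#'   when `TRUE`, unused neighbors whose neighborhood density exceeds
#'   `fluff_density` are appended, which may break module disjointness).
#' @param fluff_density Density threshold for the fluff stage (default 0.1).
#' @return A tibble of class `gene_modules` with columns `label`,
#'   `seed_gene`, `size`, `density`, `score` and a list-column `members`.
#' @export
find_modules <- function(network, k_core_filter = 4, node_score_cutoff = 0.2,
                         haircut = TRUE, fluff = FALSE, fluff_density = 0.1) {
  stopifnot(inherits(network, "ppi_network"))
  if (node_score_cutoff < 0 || node_score_cutoff >= 1) {
    parameter_error("node_score_cutoff must lie in [0, 1)")
  }
  if (k_core_filter < 1) parameter_error("k_core_filter must be >= 1")

  w <- vertex_weights(network)
  adj <- adjacency_list(network)
  # seeds in descending weight; nodes are pre-sorted, and the stable sort
  # breaks ties by lexicographically smallest name
  seed_order <- network$nodes[order(-w[network$nodes])]
  used <- setNames(logical(length(network$nodes)), network$nodes)
  raw_members <- list()
  raw_seed <- character(0)

  for (seed in seed_order) {
    if (used[[seed]]) next
    threshold <- w[[seed]] * (1 - node_score_cutoff)
    members <- seed
    used[[seed]] <- TRUE
    queue <- seed
    while (length(queue) > 0) {
      u <- queue[[1]]
      queue <- queue[-1]
      for (v in sort_c(adj[[u]])) {
        if (!used[[v]] && w[[v]] > threshold) {
          used[[v]] <- TRUE
          members <- c(members, v)
          queue <- c(queue, v)
        }
      }
    }
    if (length(members) < 2) next
    raw_members[[length(raw_members) + 1L]] <- members
    raw_seed <- c(raw_seed, seed)
  }

  out <- list()
  for (i in seq_along(raw_members)) {
    members <- raw_members[[i]]
    if (haircut) members <- haircut_members(network, members)
    if (length(members) < 2) next
    for (comp in coherent_components(network, members)) {
      comp_net <- induce_subgraph(network, comp)
      if (haircut) {
        comp <- haircut_members(network, comp)
        comp_net <- induce_subgraph(network, comp)
      }
      if (length(comp) < 2) next
      core <- k_core(comp_net, k_core_filter)
      if (length(core$nodes) == 0) next
      if (fluff) {
        extra <- character(0)
        for (v in comp) {
          for (nb in adj[[v]]) {
            if (nb %in% comp || nb %in% extra) next
            nb_net <- induce_subgraph(network, c(nb, adj[[nb]]))
            if (graph_density(nb_net) > fluff_density) extra <- c(extra, nb)
          }
        }
        comp <- sort_c(unique(c(comp, extra)))
        comp_net <- induce_subgraph(network, comp)
      }
      seed_in <- intersect(raw_seed[i], comp)
      seed_gene <- if (length(seed_in) == 1) {
        seed_in
      } else {
        # split component without the original seed: highest weight; `comp` is
        # sorted, so the stable sort breaks ties by smallest name
        comp[order(-w[comp])][1]
      }
      out[[length(out) + 1L]] <- tibble(
        seed_gene = seed_gene,
        size = length(comp),
        density = graph_density(comp_net),
        score = graph_density(comp_net) * length(comp),
        members = list(sort_c(comp))
      )
    }
  }

  if (length(out) == 0) {
    res <- tibble(label = character(0), seed_gene = character(0),
                  size = integer(0), density = numeric(0), score = numeric(0),
                  members = list())
    class(res) <- c("gene_modules", class(res))
    return(res)
  }
  res <- bind_rows(out)
  first_member <- map_chr(res$members, 1)
  res <- res[order(-res$score, -res$size, first_member, method = "radix"), ]
  res <- mutate(res, label = paste0("M", row_number())) |>
    select("label", "seed_gene", "size", "density", "score", "members")
  class(res) <- c("gene_modules", class(res))
  res
}

#' All genes belonging to any module
#' @param modules A `gene_modules` tibble from [find_modules()].
#' @return Sorted character vector.
#' @export
module_genes <- function(modules) {
  sort_c(unique(unlist(modules$members, use.names = FALSE)))
}
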