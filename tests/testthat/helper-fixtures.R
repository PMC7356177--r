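# Shared fixture builders: tiny graphs, expression sets and oracles used
# across the test files. Everything is built in code at test time.

# network from a plain edge list, default score 0.9
net_of <- function(..., nodes = character(0), score = 0.9) {
  pairs <- list(...)
  if (length(pairs) == 0) {
    return(ppi_network(nodes = nodes))
  }
  edges <- tibble::tibble(
    from = vapply(pairs, `[[`, "", 1),
    to = vapply(pairs, `[[`, "", 2),
    score = score
  )
  ppi_network(edges = edges, nodes = nodes)
}

# complete graph on the given node names
clique_net <- function(nodes, score = 0.9) {
  pairs <- utils::combn(nodes, 2)
  ppi_network(edges = tibble::tibble(from = pairs[1, ], to = pairs[2, ],
                                     score = score))
}

# Erdos-Renyi G(n, p) graph with nodes n01..nNN
random_net <- function(n, p) {
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- utils::combn(nodes, 2)
  pick <- stats::runif(ncol(pairs)) < p
  ppi_network(edges = tibble::tibble(from = pairs[1, pick],
                                     to = pairs[2, pick], score = 0.9),
              nodes = nodes)
}

# exhaustive k-core oracle for n <= 16: the k-core is the unique maximum
# subset whose induced minimum degree is >= k (the union of any two feasible
# subsets is feasible, so the maximum is the union of all of them)
k_core_oracle <- function(network, k) {
  n <- length(network$nodes)
  stopifnot(n <= 16)
  if (n == 0) return(character(0))
  A <- matrix(0L, n, n, dimnames = list(network$nodes, network$nodes))
  if (nrow(network$edges) > 0) {
    A[cbind(network$edges$from, network$edges$to)] <- 1L
    A[cbind(network$edges$to, network$edges$from)] <- 1L
  }
  n_sub <- 2^n
  # membership matrix: n x 2^n, column j = binary code of j-1
  M <- vapply(seq_len(n_sub) - 1, function(code) {
    as.integer(bitwAnd(bitwShiftR(code, 0:(n - 1)), 1L))
  }, integer(n))
  D <- A %*% M # within-subset degree of every node for every subset
  valid <- colSums(M * (D < k)) == 0
  sizes <- colSums(M)
  sizes[!valid] <- -1L
  best <- which.max(sizes)
  network$nodes[M[, best] == 1]
}

# brute-force Benjamini-Hochberg step-up, written independently of p.adjust
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  # step-up: q_i = min_{j >= i} p_(j) * n / j, capped at 1
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(1, q_sorted)
  q
}

# hypergeometric upper tail by complete enumeration of draws
hyper_tail_oracle <- function(n_universe, n_set, n_query, k_min) {
  universe <- seq_len(n_universe)
  set <- seq_len(n_set)
  draws <- utils::combn(universe, n_query)
  hits <- apply(draws, 2, function(d) sum(d %in% set))
  mean(hits >= k_min)
}

# small expression set built directly from a matrix
expr_fixture <- function(values, case, control, lnc = character(0)) {
  samples <- colnames(values)
  expr_set(
    values,
    groups = tibble::tibble(
      sample_id = samples,
      group = ifelse(samples %in% case, "case", "control")
    ),
    classes = tibble::tibble(
      feature_id = rownames(values),
      class = ifelse(rownames(values) %in% lnc, "lncRNA", "coding")
    )
  )
}

# the published five-lncRNA worked example shipped with the package
candidate_table <- function() {
  readr::read_tsv(
    system.file("extdata", "fm_lnc_candidates.tsv", package = "lncnet"),
    comment = "#", show_col_types = FALSE
  )
}
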