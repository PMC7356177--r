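# Over-representation analysis: one-sided hypergeometric upper-tail test of a
# query gene list against each set of a collection, with an optional
# Bonferroni correction across the sets tested.

#' Hypergeometric gene-set over-representation
#'
#' For each set `S` in the collection, computes the upper-tail probability
#' `P[X >= n_overlap]` where `X` is hypergeometric with population
#' `n_universe`, successes `|S` intersected with the universe`|` and draws
#' `n_query`. Query members outside the universe are dropped (a message
#' reports the count). With `correction = "bonferroni"`,
#' `p_adj = min(1, m * p_raw)` where `m` is the number of sets tested.
#'
#' Two significance regimes are in use for transcriptome enrichment reports:
#' uncorrected `p < alpha` (strict, the GO biological-process convention
#' here) and Bonferroni-corrected `p <= alpha` (the pathway convention).
#' `strict` defaults accordingly but can be overridden.
#'
#' @param query Character vector of gene symbols.
#' @param collection A [geneset_collection()].
#' @param correction `"none"` or `"bonferroni"`.
#' @param alpha Significance level (default 0.05).
#' @param strict Use strict `<` instead of `<=` when flagging significance;
#'   defaults to `TRUE` for `correction = "none"` and `FALSE` for
#'   `"bonferroni"`.
#' @return A tibble of class `enrichment_results` with columns `set_name`,
#'   `n_universe`, `n_set`, `n_query`, `n_overlap`, `p_raw`, `p_adj`,
#'   `significant`, sorted by `p_adj` then `p_raw` then `set_name`.
#' @export
hypergeometric_enrichment <- function(query, collection,
                                      correction = c("bonferroni", "none"),
                                      alpha = 0.05, strict = NULL) {
  correction <- match.arg(correction)
  stopifnot(inherits(collection, "geneset_collection"))
  if (length(collection$universe) == 0) {
    parameter_error("enrichment universe is empty")
  }
  if (is.null(strict)) strict <- correction == "none"
  query <- unique(as.character(query))
  outside <- setdiff(query, collection$universe)
  if (length(outside) > 0) {
    inform(sprintf("%d query genes outside the universe dropped", length(outside)))
    query <- intersect(query, collection$universe)
  }
  n_universe <- length(collection$universe)
  n_query <- length(query)
  m <- length(collection$sets)
  rows <- imap(collection$sets, function(members, nm) {
    set_in <- intersect(members, collection$universe)
    k <- length(intersect(set_in, query))
    p <- phyper(k - 1, length(set_in), n_universe - length(set_in), n_query,
                lower.tail = FALSE)
    tibble(set_name = nm, n_universe = n_universe, n_set = length(set_in),
           n_query = n_query, n_overlap = k, p_raw = p)
  })
  res <- bind_rows(rows) |>
    mutate(
      p_adj = if (correction == "bonferroni") pmin(1, m * .data$p_raw) else .data$p_raw,
      significant = if (strict) {
        (if (correction == "none") .data$p_raw else .data$p_adj) < alpha
      } else {
        (if (correction == "none") .data$p_raw else .data$p_adj) <= alpha
      }
    ) |>
    arrange(.data$p_adj, .data$p_raw, .data$set_name)
  class(res) <- c("enrichment_results", class(res))
  res
}
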