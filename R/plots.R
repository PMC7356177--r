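# ggplot2 autoplot methods for the pipeline's result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_col geom_tile
#'   geom_hline geom_vline labs theme_minimal scale_color_manual
#' @export
ggplot2::autoplot

#' Volcano plot of differential expression results
#'
#' @param object A `deg_results` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot deg_results
#' @export
autoplot.deg_results <- function(object, ...) {
  df <- mutate(object,
               neglog_q = -log10(pmax(.data$q_fdr, 1e-300)),
               status = dplyr::case_when(
                 .data$selected & .data$class == "lncRNA" ~ "lncRNA DEG",
                 .data$selected ~ "coding DEG",
                 TRUE ~ "not selected"
               ))
  ggplot(df, aes(x = .data$log2fc, y = .data$neglog_q,
                 color = .data$status)) +
    geom_point(alpha = 0.6, size = 1) +
    scale_color_manual(values = c("coding DEG" = "#d95f02",
                                  "lncRNA DEG" = "#7570b3",
                                  "not selected" = "grey70")) +
    geom_hline(yintercept = 2, linetype = "dashed", linewidth = 0.3) +
    geom_vline(xintercept = c(-log2(1.5), log2(1.5)),
               linetype = "dashed", linewidth = 0.3) +
    labs(x = "log2 fold change (case - control)",
         y = "-log10 q (BH)", color = NULL) +
    theme_minimal()
}

#' Bar plot of detected module scores
#'
#' @param object A `gene_modules` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gene_modules
#' @export
autoplot.gene_modules <- function(object, ...) {
  df <- mutate(object, label = factor(.data$label,
                                      levels = sort_module_labels(.data$label)))
  ggplot(df, aes(x = .data$label, y = .data$score)) +
    geom_col(fill = "#1b9e77") +
    labs(x = NULL, y = "module score (density x size)",
         subtitle = "bar per detected module") +
    theme_minimal()
}

#' Dot plot of enrichment results
#'
#' @param object An `enrichment_results` tibble.
#' @param top Number of top sets to show (default 15).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot enrichment_results
#' @export
autoplot.enrichment_results <- function(object, top = 15, ...) {
  df <- head(object, top) |>
    mutate(set_name = factor(.data$set_name, levels = rev(.data$set_name)),
           neglog_p = -log10(pmax(.data$p_adj, 1e-300)))
  ggplot(df, aes(x = .data$neglog_p, y = .data$set_name,
                 size = .data$n_overlap, color = .data$significant)) +
    geom_point() +
    labs(x = "-log10 adjusted p", y = NULL, size = "overlap",
         color = "significant") +
    theme_minimal()
}

#' Module-coverage tile plot for lncRNA candidates
#'
#' @param object An `lnc_priority` tibble after coverage.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lnc_priority
#' @export
autoplot.lnc_priority <- function(object, ...) {
  labels <- sort_module_labels(unique(unlist(object$covered_modules)))
  if (length(labels) == 0) labels <- "none"
  df <- tidyr::crossing(lnc_id = object$lnc_id, module = labels) |>
    left_join(
      tibble(lnc_id = object$lnc_id, covered = object$covered_modules),
      by = "lnc_id"
    ) |>
    mutate(hit = map2_lgl(.data$module, .data$covered, ~ .x %in% .y))
  ggplot(df, aes(x = factor(.data$module, levels = labels), y = .data$lnc_id,
                 fill = .data$hit)) +
    geom_tile(color = "white") +
    scale_fill_manual(values = c(`TRUE` = "#1b9e77", `FALSE` = "grey90")) +
    labs(x = "module", y = NULL, fill = "targets module") +
    theme_minimal()
}
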