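# End-to-end orchestration: read or generate inputs, call DEGs, build the
# DEG network, detect modules, run enrichment, run the lncRNA cascade, write
# reports and a manifest.

#' Run the full prioritization pipeline
#'
#' Stage order: input (read or generate) -> differential expression ->
#' DEG selection and class split -> DEG network induction -> module
#' detection -> enrichment (DEG list and each module, when gene sets are
#' available) -> lncRNA cascade -> reports. One structured log line per
#' stage reports input/output cardinalities so a run's funnel (DEGs ->
#' connected DEGs -> modules; lncRNA DEGs -> candidates -> prioritized) can
#' be read from the log.
#'
#' @param config A [run_config()] (or a `generator_config`, treated as
#'   `run_config(generate = config)`).
#' @param out_dir Output directory (overrides `config$out_dir`); `NULL` to
#'   skip writing files.
#' @param quiet Suppress stage log lines.
#' @return An object of class `lncnet_run`: list with `deg` (deg_results),
#'   `deg_sets`, `network`, `deg_network`, `n_connected`, `modules`,
#'   `enrichment` (named list), `lnc_records` (lnc_priority),
#'   `priority_table`, `prioritized` (ids), `manifest`, `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  if (inherits(config, "generator_config")) {
    config <- run_config(generate = config, seed = config$seed)
  }
  stopifnot(inherits(config, "run_config"))
  out_dir <- out_dir %||% config$out_dir
  say <- function(stage, ...) {
    if (!quiet) inform(sprintf("[%s] %s", stage, sprintf(...)))
  }

  if (!is.null(config$generate)) {
    study <- synthesize_study(config$generate)
    expr <- study$expr
    network <- study$network
    annotation <- study$annotation
    genesets <- study$genesets
  } else {
    expr <- read_expression(config$expression, config$groups, config$classes)
    network <- read_edge_list(config$edges, min_score = config$edge_min_score)
    annotation <- read_regulatory(config$lnc_mirna, config$lnc_gene,
                                  config$mirna_gene)
    genesets <- if (!is.null(config$gene_sets)) read_gmt(config$gene_sets) else NULL
    study <- NULL
  }
  say("input", "%d features x %d samples; %d network edges",
      nrow(expr$values), ncol(expr$values), nrow(network$edges))

  deg <- compute_differential(expr) |>
    select_degs(fc_min = config$deg_fc_min, q_max = config$deg_q_max)
  deg_sets <- split_by_class(deg)
  say("deg", "%d selected (%d coding, %d lncRNA) of %d features",
      sum(deg$selected), length(deg_sets$coding), length(deg_sets$lncRNA),
      nrow(deg))

  deg_network <- induce_deg_network(network, deg_sets$coding)
  n_connected <- count_connected(deg_network)
  say("network", "%d coding DEGs in network, %d functionally connected",
      length(deg_network$nodes), n_connected)

  modules <- find_modules(deg_network,
                          k_core_filter = config$mcode_k_core,
                          node_score_cutoff = config$mcode_cutoff,
                          haircut = config$mcode_haircut,
                          fluff = config$mcode_fluff)
  say("modules", "%d modules (sizes: %s)", nrow(modules),
      paste(modules$size, collapse = ", "))

  enrichment <- list()
  if (!is.null(genesets)) {
    enrichment$degs <- hypergeometric_enrichment(
      deg_sets$coding, genesets,
      correction = config$enrichment_deg_correction,
      alpha = config$enrichment_deg_alpha
    )
    for (i in seq_len(nrow(modules))) {
      enrichment[[modules$label[i]]] <- hypergeometric_enrichment(
        modules$members[[i]], genesets,
        correction = config$enrichment_module_correction,
        alpha = config$enrichment_module_alpha
      )
    }
    say("enrichment", "%d gene lists tested against %d sets",
        length(enrichment), length(genesets$sets))
  }

  lnc_degs <- filter(deg, .data$selected, .data$class == "lncRNA")
  lnc_records <- prioritize_lncrnas(lnc_degs, annotation, deg_sets$coding,
                                    modules, fc_min = config$lnc_fc_min)
  prioritized <- lnc_records$lnc_id[lnc_records$prioritized]
  candidates <- lnc_records$lnc_id[lnc_records$passed_fc & lnc_records$passed_mirna]
  say("lncRNA", "%d modulated -> %d candidates -> %d prioritized",
      nrow(lnc_records), length(candidates), length(prioritized))

  run <- structure(list(
    deg = deg,
    deg_sets = deg_sets,
    network = network,
    deg_network = deg_network,
    n_connected = n_connected,
    modules = modules,
    enrichment = enrichment,
    lnc_records = lnc_records,
    priority_table = render_priority_table(lnc_records),
    prioritized = prioritized,
    truth = if (!is.null(study)) study$truth else NULL,
    config = config,
    manifest = NULL
  ), class = "lncnet_run")

  if (!is.null(out_dir)) {
    run$manifest <- write_run(run, out_dir)
    say("report", "artifacts written to %s", out_dir)
  }
  run
}

#' @export
print.lncnet_run <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<lncnet_run> %d/%d features selected; %d connected coding DEGs; %d modules; %d lncRNAs prioritized\n",
    g$n_selected, g$n_features, g$n_connected, g$n_modules, g$n_prioritized
  ))
  if (g$n_prioritized > 0) {
    cat("  prioritized:", paste(x$prioritized, collapse = ", "), "\n")
  }
  invisible(x)
}

# serialize all run artifacts; returns the manifest
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  put <- function(name) {
    files <<- c(files, name)
    file.path(out_dir, name)
  }
  readr::write_tsv(
    run$deg |> select("feature_id", "class", "fc", "log2fc", "p_raw",
                      "q_fdr", "selected"),
    put("degs.tsv"), progress = FALSE
  )
  readr::write_tsv(
    run$modules |>
      mutate(members = map_chr(.data$members, paste, collapse = ",")) |>
      select("label", "seed_gene", "size", "density", "score", "members"),
    put("modules.tsv"), progress = FALSE
  )
  jsonlite::write_json(
    list(n_nodes = length(run$deg_network$nodes),
         n_edges = nrow(run$deg_network$edges),
         n_connected_degs = run$n_connected),
    put("network_stats.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  for (nm in names(run$enrichment)) {
    readr::write_tsv(run$enrichment[[nm]],
                     put(paste0("enrichment_", nm, ".tsv")), progress = FALSE)
  }
  lnc_out <- run$priority_table |>
    dplyr::bind_cols(run$lnc_records |>
                       select("passed_fc", "passed_mirna", "passed_deg",
                              "prioritized"))
  readr::write_tsv(lnc_out, put("lnc_priority.tsv"), progress = FALSE)
  readr::write_lines(run$prioritized, put("prioritized.txt"))

  g <- glance(run)
  cfg <- unclass(run$config)
  cfg$generate <- if (!is.null(cfg$generate)) unclass(cfg$generate) else NULL
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                               null = "null")
  manifest <- list(
    seed = run$config$seed,
    config = cfg,
    config_hash = unname(tools::md5sum(textConnection_md5(cfg_json))),
    stage_counts = as.list(g),
    checksums = as.list(setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files
    ))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

# md5 of a string via a temp file (tools::md5sum only takes paths)
textConnection_md5 <- function(x) {
  tf <- tempfile()
  writeLines(as.character(x), tf)
  tf
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pipeline run
#'
#' One row per modulated lncRNA: the rendered priority table joined with the
#' cascade pass flags.
#'
#' @param x An `lncnet_run`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy lncnet_run
#' @export
tidy.lncnet_run <- function(x, ...) {
  dplyr::bind_cols(
    x$priority_table,
    x$lnc_records |>
      select("passed_fc", "passed_mirna", "passed_deg", "prioritized")
  )
}

#' One-row summary of a pipeline run
#'
#' The run funnel: feature and DEG counts, connected DEGs, module count,
#' lncRNA candidate and prioritized counts.
#'
#' @param x An `lncnet_run`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance lncnet_run
#' @export
glance.lncnet_run <- function(x, ...) {
  tibble(
    n_features = nrow(x$deg),
    n_selected = sum(x$deg$selected),
    n_coding_degs = length(x$deg_sets$coding),
    n_lnc_degs = length(x$deg_sets$lncRNA),
    n_connected = x$n_connected,
    n_modules = nrow(x$modules),
    n_lnc_candidates = sum(x$lnc_records$passed_fc & x$lnc_records$passed_mirna),
    n_prioritized = length(x$prioritized)
  )
}
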