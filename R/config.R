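# Run configuration: defaults, YAML parsing, range checks.

run_config_defaults <- function() {
  list(
    # input files (all five required together) ...
    expression = NULL, groups = NULL, classes = NULL, edges = NULL,
    lnc_mirna = NULL, lnc_gene = NULL, mirna_gene = NULL, gene_sets = NULL,
    # ... or a generator section
    generate = NULL,
    deg_fc_min = 1.5,
    deg_q_max = 0.01,
    edge_min_score = 0.4,
    mcode_k_core = 4,
    mcode_cutoff = 0.2,
    mcode_haircut = TRUE,
    mcode_fluff = FALSE,
    lnc_fc_min = 4,
    enrichment_deg_correction = "none",
    enrichment_deg_alpha = 0.05,
    enrichment_module_correction = "bonferroni",
    enrichment_module_alpha = 0.05,
    out_dir = NULL,
    seed = 17
  )
}

#' Build a run configuration
#'
#' Thresholds default to the pipeline's reference values: DEG selection at
#' `|FC| >= 1.5` and `q <= 0.01`, edge score `>= 0.4`, module detection with
#' k-core filter 4 and node score cutoff 0.2 (haircut on, fluff off), and the
#' lncRNA fold-change gate at `|FC| >= 4`. Exactly one of the input-path set
#' or a `generate` section must be present.
#'
#' @param ... Named overrides of the defaults (see
#'   [validate_config()] for the key list). `generate` may be a
#'   [generator_config()] or a named list of its arguments.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(...) {
  overrides <- list(...)
  defaults <- run_config_defaults()
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    config_error(paste0("unknown config key: ", unknown[1]))
  }
  cfg <- modifyList(defaults, overrides, keep.null = TRUE)
  check_run_config(cfg)
}

check_run_config <- function(cfg) {
  num_in <- function(key, lo, hi) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < lo || v > hi) {
      config_error(sprintf("config value out of range: %s", key))
    }
  }
  num_in("deg_fc_min", 1, Inf)
  num_in("deg_q_max", 0, 1)
  num_in("edge_min_score", 0, 1)
  num_in("mcode_k_core", 1, Inf)
  num_in("mcode_cutoff", 0, 1 - 1e-12)
  num_in("lnc_fc_min", 1, Inf)
  num_in("enrichment_deg_alpha", 0, 1)
  num_in("enrichment_module_alpha", 0, 1)
  for (key in c("enrichment_deg_correction", "enrichment_module_correction")) {
    if (!cfg[[key]] %in% c("none", "bonferroni")) {
      config_error(paste0("config value out of range: ", key))
    }
  }
  path_keys <- c("expression", "groups", "classes", "edges",
                 "lnc_mirna", "lnc_gene", "mirna_gene")
  has_paths <- any(!map_lgl(cfg[path_keys], is.null))
  has_gen <- !is.null(cfg$generate)
  if (has_paths && has_gen) {
    config_error("config must give either input paths or a generate section, not both")
  }
  if (!has_paths && !has_gen) {
    config_error("config must give input paths or a generate section")
  }
  if (has_paths) {
    missing <- path_keys[map_lgl(cfg[path_keys], is.null)]
    if (length(missing) > 0) {
      config_error(paste0("missing input path: ", missing[1]))
    }
  }
  if (has_gen && !inherits(cfg$generate, "generator_config")) {
    if (!is.list(cfg$generate)) config_error("generate must be a named list")
    cfg$generate <- do.call(generator_config,
                            c(cfg$generate,
                              if (is.null(cfg$generate$seed)) list(seed = cfg$seed)))
  }
  structure(cfg, class = "run_config")
}

#' Read and validate a YAML run configuration
#'
#' Unknown keys are rejected; an empty file yields all documented defaults
#' plus a default generate section.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) lnc_abort(paste0("file not found: ", path), "lncnet_io_error")
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) config_error("config file must be a YAML mapping")
  if (is.null(raw$generate) &&
      !any(names(raw) %in% c("expression", "groups", "classes", "edges",
                             "lnc_mirna", "lnc_gene", "mirna_gene"))) {
    raw$generate <- list()
  }
  do.call(run_config, raw)
}
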