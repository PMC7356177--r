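# Synthetic study generator with planted ground truth: a case/control log2
# expression matrix with planted differentially expressed features, a PPI
# network with planted dense modules, and a regulatory annotation with
# planted lncRNA -> miRNA -> gene chains from "driver" lncRNAs into every
# module, plus one decoy lncRNA per cascade failure mode. All randomness
# flows from one root seed through child_seed() streams (1 cohort, 2 network,
# 3 regulatory annotation, 4 gene sets).

#' Generator configuration
#'
#' Defaults define the reference synthetic study: 2000 coding and 300 lncRNA
#' features, 10 case vs 10 control samples, 5% planted DE with linear fold
#' changes in `[1.8, 6]`, Gaussian log2 noise with sd 0.3, six planted
#' 8-gene modules, sparse background interactions, two driver lncRNAs and
#' four decoys.
#'
#' @param n_coding,n_lnc Feature counts.
#' @param n_case,n_control Sample counts.
#' @param frac_de Proportion of features planted DE, in `[0, 0.5]` (0 gives a
#'   null cohort with no planted signal; module_count must then be 0).
#' @param fc_range Linear fold-change magnitude interval for planted DE.
#' @param driver_fc_min Minimum planted `|FC|` for driver lncRNAs (>= 4);
#'   drivers are planted at `max(driver_fc_min, fc_range[2])`.
#' @param noise_sd Standard deviation of i.i.d. Gaussian log2 noise.
#' @param module_count,module_size Planted module geometry (module_size >= 6
#'   when modules are planted).
#' @param background_edge_p Background edge probability.
#' @param n_driver Number of driver lncRNAs.
#' @param seed Integer root seed.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_coding = 2000, n_lnc = 300, n_case = 10,
                             n_control = 10, frac_de = 0.05,
                             fc_range = c(1.8, 6), driver_fc_min = 4.5,
                             noise_sd = 0.3, module_count = 6,
                             module_size = 8, background_edge_p = 0.01,
                             n_driver = 2, seed = 17) {
  cfg <- list(
    n_coding = as.integer(n_coding), n_lnc = as.integer(n_lnc),
    n_case = as.integer(n_case), n_control = as.integer(n_control),
    frac_de = frac_de, fc_range = as.numeric(fc_range),
    driver_fc_min = driver_fc_min, noise_sd = noise_sd,
    module_count = as.integer(module_count),
    module_size = as.integer(module_size),
    background_edge_p = background_edge_p,
    n_driver = as.integer(n_driver), seed = as.integer(seed)
  )
  with(cfg, {
    if (n_coding < 1 || n_lnc < 1 || n_case < 1 || n_control < 1) {
      config_error("feature and sample counts must be positive")
    }
    if (frac_de < 0 || frac_de > 0.5) config_error("frac_de must lie in [0, 0.5]")
    if (frac_de == 0 && module_count > 0) {
      config_error("a null cohort (frac_de = 0) cannot plant modules")
    }
    if (length(fc_range) != 2 || fc_range[1] <= 1.5 || fc_range[2] < fc_range[1]) {
      config_error("fc_range lower bound must exceed 1.5")
    }
    if (driver_fc_min < 4) config_error("driver_fc_min must be >= 4")
    if (noise_sd < 0) config_error("noise_sd must be >= 0")
    if (module_count < 0 || module_size < 0 || background_edge_p < 0 ||
        background_edge_p > 1) {
      config_error("module geometry / edge probability out of range")
    }
    if (n_driver < 1) config_error("n_driver must be >= 1")
  })
  structure(cfg, class = "generator_config")
}

n_decoys <- 4L # one per cascade failure mode: fc, mirna, deg target, coverage

#' Generate a synthetic case/control cohort
#'
#' Baseline log2 means are drawn uniform in `[5, 12]` per feature; planted DE
#' features are shifted by `log2(FC)` in case samples (sign per up/down);
#' i.i.d. Gaussian log2 noise with sd `noise_sd` is added everywhere.
#' Deterministic given the config seed.
#'
#' @param config A [generator_config()].
#' @return List with `expr` (an [expr_set()]) and `truth` (the planted-truth
#'   bundle: `de_up`, `de_down`, `planted_fc` named vector of signed linear
#'   fold changes, `planted_modules`, `driver_lncs`, `decoy_lncs` named by
#'   failure mode, `planted_chains`, plus the feature id universes and
#'   `seed`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(child_seed(config$seed, 1))
  coding <- sprintf("G%05d", seq_len(config$n_coding))
  lnc <- sprintf("LNC%04d", seq_len(config$n_lnc))
  samples <- c(sprintf("FM%02d", seq_len(config$n_case)),
               sprintf("HC%02d", seq_len(config$n_control)))
  groups <- rep(c("case", "control"), c(config$n_case, config$n_control))

  n_de_coding <- round(config$frac_de * config$n_coding)
  n_de_lnc <- round(config$frac_de * config$n_lnc)
  n_module_genes <- config$module_count * config$module_size
  if (n_de_coding < n_module_genes) {
    config_error("not enough planted DE coding genes to fill the modules")
  }
  de_coding <- if (n_de_coding > 0) sample(coding, n_de_coding) else character(0)
  de_lnc <- if (n_de_lnc > 0) sample(lnc, n_de_lnc) else character(0)

  planted_modules <- list()
  if (config$module_count > 0) {
    for (i in seq_len(config$module_count)) {
      idx <- ((i - 1) * config$module_size + 1):(i * config$module_size)
      planted_modules[[i]] <- sort_c(de_coding[idx])
    }
  }

  driver_lncs <- character(0)
  decoy_lncs <- character(0)
  if (config$module_count > 0) {
    if (n_de_lnc < config$n_driver + n_decoys) {
      config_error("not enough planted DE lncRNAs for drivers and decoys")
    }
    driver_lncs <- de_lnc[seq_len(config$n_driver)]
    decoy_lncs <- setNames(
      de_lnc[config$n_driver + seq_len(n_decoys)],
      c("fc", "mirna", "deg", "coverage")
    )
  }

  de_all <- c(de_coding, de_lnc)
  fc_mag <- runif(length(de_all), config$fc_range[1], config$fc_range[2])
  names(fc_mag) <- de_all
  # drivers and the structural decoys are planted at the top of the FC range
  # so the |FC| >= 4 gate reflects design, not sampling noise; the low-FC
  # decoy sits far below the gate for the same reason
  strong <- c(driver_lncs, unname(decoy_lncs[c("mirna", "deg", "coverage")]))
  fc_mag[strong] <- max(config$driver_fc_min, config$fc_range[2])
  if (length(decoy_lncs) > 0) {
    fc_mag[decoy_lncs[["fc"]]] <- min(max(2.5, config$fc_range[1]), 3.5)
  }
  sign_de <- sample(c(-1, 1), length(de_all), replace = TRUE)
  names(sign_de) <- de_all
  planted_fc <- fc_mag * sign_de

  baseline <- runif(length(c(coding, lnc)), 5, 12)
  values <- matrix(
    baseline + rnorm(length(baseline) * length(samples), 0, config$noise_sd),
    nrow = length(baseline), ncol = length(samples),
    dimnames = list(c(coding, lnc), samples)
  )
  if (length(de_all) > 0) {
    shift <- sign_de * log2(fc_mag)
    values[de_all, groups == "case"] <-
      values[de_all, groups == "case"] + shift
  }

  expr <- expr_set(
    values,
    groups = tibble(sample_id = samples, group = groups),
    classes = tibble(feature_id = c(coding, lnc),
                     class = rep(c("coding", "lncRNA"),
                                 c(length(coding), length(lnc))))
  )
  truth <- structure(list(
    de_up = sort_c(de_all[sign_de > 0]),
    de_down = sort_c(de_all[sign_de < 0]),
    planted_fc = planted_fc,
    planted_modules = planted_modules,
    driver_lncs = driver_lncs,
    decoy_lncs = decoy_lncs,
    planted_chains = tibble(lnc_id = character(0), mirna_id = character(0),
                            gene = character(0)),
    coding_features = coding,
    lnc_features = lnc,
    de_coding = sort_c(de_coding),
    de_lnc = sort_c(de_lnc),
    seed = config$seed
  ), class = "truth_bundle")
  list(expr = expr, truth = truth)
}

#' Generate the synthetic interaction network
#'
#' Each planted module is a clique over its members with 10% edge dropout,
#' constrained so every member keeps within-module degree >= 4 (hence
#' `module_size >= 6`). Background edges are added with probability
#' `background_edge_p` among the planted DE coding genes plus a margin of 50
#' non-DE coding genes, excluding pairs in which both endpoints belong to
#' planted modules (so the planted density structure stays unambiguous).
#' Within-module scores are drawn in `[0.7, 0.99]`, background scores in
#' `[0.4, 0.7]`.
#'
#' @param truth Truth bundle from [generate_cohort()].
#' @param config The same [generator_config()].
#' @return A [ppi_network()].
#' @export
generate_network <- function(truth, config) {
  stopifnot(inherits(config, "generator_config"))
  if (config$module_count > 0 && config$module_size < 6) {
    config_error("module_size must be >= 6 to guarantee a 4-core after dropout")
  }
  set.seed(child_seed(config$seed, 2))
  edges <- list()
  module_members <- unlist(truth$planted_modules, use.names = FALSE)
  for (mod in truth$planted_modules) {
    pairs <- utils::combn(mod, 2)
    keep <- rep(TRUE, ncol(pairs))
    # dropout removes a random matching: at most 10% of clique edges, and no
    # member loses more than one within-module edge, so every member keeps
    # degree >= size - 2 (>= 4 for module_size >= 6) and the members' MCODE
    # weights stay homogeneous enough that dropout cannot fragment the module
    n_drop <- min(floor(0.1 * ncol(pairs)), floor(length(mod) / 2))
    if (n_drop > 0) {
      perm <- sample(mod)
      for (j in seq_len(n_drop)) {
        a <- perm[2 * j - 1]; b <- perm[2 * j]
        keep[(pairs[1, ] == a & pairs[2, ] == b) |
               (pairs[1, ] == b & pairs[2, ] == a)] <- FALSE
      }
    }
    kept <- pairs[, keep, drop = FALSE]
    edges[[length(edges) + 1L]] <- tibble(
      from = kept[1, ], to = kept[2, ],
      score = runif(ncol(kept), 0.7, 0.99)
    )
  }
  non_de <- setdiff(truth$coding_features, truth$de_coding)
  margin <- if (length(non_de) > 0) sample(non_de, min(50, length(non_de))) else character(0)
  bg_nodes <- sort_c(c(truth$de_coding, margin))
  if (length(bg_nodes) >= 2 && config$background_edge_p > 0) {
    pairs <- utils::combn(bg_nodes, 2)
    both_mod <- pairs[1, ] %in% module_members & pairs[2, ] %in% module_members
    pick <- runif(ncol(pairs)) < config$background_edge_p & !both_mod
    kept <- pairs[, pick, drop = FALSE]
    if (ncol(kept) > 0) {
      edges[[length(edges) + 1L]] <- tibble(
        from = kept[1, ], to = kept[2, ],
        score = runif(ncol(kept), 0.4, 0.7)
      )
    }
  }
  all_edges <- if (length(edges) > 0) bind_rows(edges) else empty_edges()
  ppi_network(edges = all_edges, nodes = bg_nodes)
}

#' Generate the synthetic regulatory annotation
#'
#' For each driver lncRNA, chains `driver -> miRNA -> gene` are planted into
#' every planted module (one dedicated miRNA per driver/module pair, each
#' targeting two module genes), plus two direct lncRNA->gene interactions
#' with DE coding genes. Decoys exercise each cascade failure mode exactly
#' once: `fc` (|FC| below the gate, otherwise full chains), `mirna` (no
#' lncRNA-miRNA pair, only direct DEG targets), `deg` (miRNA and direct
#' targets that all miss the DEG set), `coverage` (chains into all modules
#' but the last). Twenty noise lncRNA-miRNA pairs among non-DE lncRNAs with
#' their own miRNA->gene targets are added as background.
#'
#' @param truth Truth bundle from [generate_cohort()].
#' @param config The same [generator_config()].
#' @return A [regulatory_annotation()] with the planted chain triples in
#'   `attr(, "planted_chains")`.
#' @export
generate_regulatory <- function(truth, config) {
  stopifnot(inherits(config, "generator_config"))
  if (config$module_count == 0) {
    config_error("cannot plant regulatory chains with module_count = 0")
  }
  set.seed(child_seed(config$seed, 3))
  mirna_id <- local({
    counter <- 0L
    function() {
      counter <<- counter + 1L
      sprintf("miR-%04d", counter)
    }
  })
  lnc_mirna <- list(); lnc_gene <- list(); mirna_gene <- list(); chains <- list()

  plant_chains <- function(lnc, module_idx) {
    for (i in module_idx) {
      m <- mirna_id()
      genes <- sample(truth$planted_modules[[i]], 2)
      lnc_mirna[[length(lnc_mirna) + 1L]] <<- tibble(lnc_id = lnc, mirna_id = m)
      mirna_gene[[length(mirna_gene) + 1L]] <<- tibble(mirna_id = m, gene = genes)
      chains[[length(chains) + 1L]] <<- tibble(lnc_id = lnc, mirna_id = m,
                                               gene = genes)
    }
  }

  all_idx <- seq_len(config$module_count)
  for (d in truth$driver_lncs) {
    plant_chains(d, all_idx)
    direct <- sample(truth$de_coding, 2)
    lnc_gene[[length(lnc_gene) + 1L]] <- tibble(lnc_id = d, gene = direct)
  }
  dec <- truth$decoy_lncs
  plant_chains(dec[["fc"]], all_idx)
  lnc_gene[[length(lnc_gene) + 1L]] <- tibble(
    lnc_id = dec[["mirna"]], gene = sample(truth$de_coding, 2)
  )
  non_de <- setdiff(truth$coding_features, truth$de_coding)
  for (i in 1:2) {
    m <- mirna_id()
    lnc_mirna[[length(lnc_mirna) + 1L]] <- tibble(lnc_id = dec[["deg"]],
                                                  mirna_id = m)
    mirna_gene[[length(mirna_gene) + 1L]] <- tibble(mirna_id = m,
                                                    gene = sample(non_de, 3))
  }
  lnc_gene[[length(lnc_gene) + 1L]] <- tibble(lnc_id = dec[["deg"]],
                                              gene = sample(non_de, 2))
  if (config$module_count > 1) {
    plant_chains(dec[["coverage"]], all_idx[-config$module_count])
  }

  noise_lncs <- setdiff(truth$lnc_features, truth$de_lnc)
  if (length(noise_lncs) > 0) {
    for (l in sample(noise_lncs, min(20, length(noise_lncs)))) {
      m <- mirna_id()
      lnc_mirna[[length(lnc_mirna) + 1L]] <- tibble(lnc_id = l, mirna_id = m)
      mirna_gene[[length(mirna_gene) + 1L]] <- tibble(
        mirna_id = m, gene = sample(truth$coding_features, 3)
      )
    }
  }

  ann <- regulatory_annotation(
    lnc_mirna = bind_rows(lnc_mirna),
    lnc_gene = bind_rows(lnc_gene),
    mirna_gene = bind_rows(mirna_gene)
  )
  attr(ann, "planted_chains") <- bind_rows(chains)
  ann
}

#' Generate synthetic gene-set collections
#'
#' One set per planted module (its members plus five random coding genes) and
#' ten random 20-gene decoy sets; the universe is all coding features.
#'
#' @param truth Truth bundle from [generate_cohort()].
#' @param config The same [generator_config()].
#' @return A [geneset_collection()].
#' @export
generate_genesets <- function(truth, config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(child_seed(config$seed, 4))
  sets <- list()
  for (i in seq_along(truth$planted_modules)) {
    sets[[sprintf("MODULE_SET_%d", i)]] <- unique(c(
      truth$planted_modules[[i]], sample(truth$coding_features, 5)
    ))
  }
  for (i in 1:10) {
    sets[[sprintf("RANDOM_SET_%02d", i)]] <- sample(truth$coding_features, 20)
  }
  geneset_collection(sets, universe = truth$coding_features)
}

#' Generate a complete synthetic study
#'
#' Runs [generate_cohort()], [generate_network()], [generate_regulatory()]
#' and [generate_genesets()] from one config and assembles the truth bundle
#' (including the planted chain triples).
#'
#' @param config A [generator_config()].
#' @return List with `expr`, `truth`, `network`, `annotation`, `genesets`,
#'   `config`.
#' @export
synthesize_study <- function(config = generator_config()) {
  cohort <- generate_cohort(config)
  network <- generate_network(cohort$truth, config)
  annotation <- generate_regulatory(cohort$truth, config)
  cohort$truth$planted_chains <- attr(annotation, "planted_chains")
  genesets <- generate_genesets(cohort$truth, config)
  list(expr = cohort$expr, truth = cohort$truth, network = network,
       annotation = annotation, genesets = genesets, config = config)
}

#' Write a synthetic study as a fixture directory
#'
#' Emits every pipeline input in the package's TSV/GMT dialects plus
#' `truth.json` and `manifest.json` (paths and seed). Refuses to write into a
#' non-empty directory unless `force = TRUE`.
#'
#' @param dir Target directory.
#' @param study Output of [synthesize_study()].
#' @param force Overwrite a non-empty directory.
#' @return The manifest (named list), invisibly.
#' @export
write_fixture <- function(dir, study, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force) {
    lnc_abort(paste0("directory not empty (use force = TRUE): ", dir),
              "lncnet_io_error")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    groups = file.path(dir, "groups.tsv"),
    classes = file.path(dir, "classes.tsv"),
    edges = file.path(dir, "ppi_edges.tsv"),
    lnc_mirna = file.path(dir, "lnc_mirna.tsv"),
    lnc_gene = file.path(dir, "lnc_gene.tsv"),
    mirna_gene = file.path(dir, "mirna_gene.tsv"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    truth = file.path(dir, "truth.json"),
    manifest = file.path(dir, "manifest.json")
  )
  write_expression(study$expr, paths$expression, paths$groups, paths$classes)
  write_edge_list(study$network, paths$edges)
  write_regulatory(study$annotation, paths$lnc_mirna, paths$lnc_gene,
                   paths$mirna_gene)
  write_gmt(study$genesets, paths$gene_sets)
  truth_json <- list(
    de_up = study$truth$de_up,
    de_down = study$truth$de_down,
    planted_fc = as.list(study$truth$planted_fc),
    planted_modules = study$truth$planted_modules,
    driver_lncs = study$truth$driver_lncs,
    decoy_lncs = as.list(study$truth$decoy_lncs),
    planted_chains = study$truth$planted_chains,
    seed = study$truth$seed
  )
  jsonlite::write_json(truth_json, paths$truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- list(
    seed = study$config$seed,
    config = unclass(study$config),
    files = lapply(paths[setdiff(names(paths), "manifest")], basename)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
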