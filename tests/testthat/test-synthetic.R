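small_cfg <- function(seed = 17, ...) {
  args <- utils::modifyList(
    list(n_coding = 400, n_lnc = 80, frac_de = 0.2, module_count = 3,
         module_size = 6, n_driver = 2, seed = seed),
    list(...)
  )
  do.call(generator_config, args)
}

test_that("config validation enforces the documented ranges", {
  expect_error(generator_config(frac_de = 0.6), class = "lncnet_config_error")
  expect_error(generator_config(fc_range = c(1.2, 6)), class = "lncnet_config_error")
  expect_error(generator_config(driver_fc_min = 3), class = "lncnet_config_error")
  expect_error(generator_config(n_case = 0), class = "lncnet_config_error")
  expect_error(generator_config(frac_de = 0), class = "lncnet_config_error")
  expect_silent(generator_config(frac_de = 0, module_count = 0))
  # not enough DE genes to fill the modules
  expect_error(
    generate_cohort(generator_config(n_coding = 100, frac_de = 0.05,
                                     module_count = 6, module_size = 8)),
    class = "lncnet_config_error"
  )
  cfg <- small_cfg()
  cohort <- generate_cohort(cfg)
  expect_error(
    generate_network(cohort$truth, small_cfg(module_size = 5)),
    class = "lncnet_config_error"
  )
  null_cfg <- generator_config(n_coding = 50, n_lnc = 10, frac_de = 0,
                               module_count = 0, seed = 1)
  expect_error(generate_regulatory(generate_cohort(null_cfg)$truth, null_cfg),
               class = "lncnet_config_error")
})

test_that("zero-noise planted fold changes are exact in the group means", {
  cfg <- small_cfg(noise_sd = 0)
  cohort <- generate_cohort(cfg)
  x <- cohort$expr
  case <- rowMeans(x$values[, x$groups == "case"])
  ctrl <- rowMeans(x$values[, x$groups == "control"])
  fcs <- cohort$truth$planted_fc
  expect_equal(unname((case - ctrl)[names(fcs)]),
               unname(sign(fcs) * log2(abs(fcs))))
  # one specific feature: planted |FC| 4 -> log2 difference exactly 2
  four <- names(fcs)[abs(abs(fcs) - 4) == min(abs(abs(fcs) - 4))][1]
  expect_equal(abs(case[[four]] - ctrl[[four]]), log2(abs(fcs[[four]])))
})

test_that("generation is deterministic and whole fixtures are byte-identical", {
  a <- synthesize_study(small_cfg())
  b <- synthesize_study(small_cfg())
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$network, b$network)
  expect_identical(a$annotation$lnc_mirna, b$annotation$lnc_mirna)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixture(d1, a)
  write_fixture(d2, b)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # refuses to clobber a non-empty directory without force
  expect_error(write_fixture(d1, a), class = "lncnet_io_error")
  expect_silent(write_fixture(d1, a, force = TRUE))
})

test_that("empirical fold changes are calibrated to the planted values", {
  cfg <- generator_config(seed = 17)
  cohort <- generate_cohort(cfg)
  x <- cohort$expr
  diffs <- rowMeans(x$values[, x$groups == "case"]) -
    rowMeans(x$values[, x$groups == "control"])
  fcs <- cohort$truth$planted_fc
  delta <- diffs[names(fcs)] - sign(fcs) * log2(abs(fcs))
  # the log2 FC estimator has standard error noise_sd * sqrt(1/n1 + 1/n2);
  # deviations should be unbiased and 95%-calibrated against it
  se <- cfg$noise_sd * sqrt(1 / cfg$n_case + 1 / cfg$n_control)
  expect_lt(abs(mean(delta)), 3 * se / sqrt(length(delta)))
  expect_gte(mean(abs(delta) <= 2.5 * se), 0.95)
  # the share landing within +/-10% of the planted linear FC matches the
  # analytic expectation P(|Z| <= log2(1.1) / se), not a higher figure
  analytic <- 2 * pnorm(log2(1.1) / se) - 1
  expect_equal(mean(abs(delta) <= log2(1.1)), analytic, tolerance = 0.15)
})

test_that("planted truth invariants hold across random configs", {
  withr::local_seed(99)
  for (i in 1:20) {
    cfg <- generator_config(
      n_coding = sample(300:600, 1), n_lnc = sample(60:120, 1),
      frac_de = runif(1, 0.15, 0.3),
      module_count = sample(2:4, 1), module_size = sample(6:9, 1),
      n_driver = sample(1:3, 1), seed = sample(1e6, 1)
    )
    study <- synthesize_study(cfg)
    tr <- study$truth
    expect_equal(length(intersect(tr$de_up, tr$de_down)), 0)
    de_coding <- intersect(c(tr$de_up, tr$de_down), tr$coding_features)
    for (mod in tr$planted_modules) {
      expect_true(all(mod %in% de_coding))
      # every planted module still holds a 4-core after dropout
      sub <- induce_deg_network(study$network, mod)
      expect_setequal(k_core(sub, 4)$nodes, k_core_oracle(sub, 4))
      expect_gt(length(k_core(sub, 4)$nodes), 0)
      expect_true(all(lncnet:::node_degrees(sub) >= 4))
    }
    # every driver has a chain into every planted module
    ch <- tr$planted_chains
    for (d in tr$driver_lncs) {
      genes <- ch$gene[ch$lnc_id == d]
      hit <- vapply(tr$planted_modules,
                    function(m) length(intersect(m, genes)) > 0, TRUE)
      expect_true(all(hit))
    }
    expect_true(all(abs(tr$planted_fc[tr$driver_lncs]) >= cfg$driver_fc_min))
    expect_lt(abs(tr$planted_fc[[tr$decoy_lncs[["fc"]]]]), 4)
    # decoy (b) has no miRNA pair, and only it lacks one among the planted set
    expect_false(tr$decoy_lncs[["mirna"]] %in% study$annotation$lnc_mirna$lnc_id)
    expect_true(all(c(tr$driver_lncs, tr$decoy_lncs[c("fc", "deg", "coverage")])
                    %in% study$annotation$lnc_mirna$lnc_id))
  }
})

test_that("module-free background cannot produce planted-module edges twice", {
  study <- synthesize_study(small_cfg(background_edge_p = 0))
  # with background off, the edge set is exactly the union of module edges
  members <- unlist(study$truth$planted_modules)
  expect_true(all(study$network$edges$from %in% members))
  expect_true(all(study$network$edges$to %in% members))
  same_mod <- vapply(seq_len(nrow(study$network$edges)), function(i) {
    any(vapply(study$truth$planted_modules, function(m) {
      study$network$edges$from[i] %in% m && study$network$edges$to[i] %in% m
    }, TRUE))
  }, TRUE)
  expect_true(all(same_mod))

  # zero dropout at size 6 would be a full clique: dropout removes at most
  # floor(0.1 * 15) = 1 edge per module here
  for (m in study$truth$planted_modules) {
    sub <- induce_deg_network(study$network, m)
    expect_gte(nrow(sub$edges), choose(6, 2) - 1)
  }
})

test_that("fixtures round-trip through the io readers", {
  study <- synthesize_study(small_cfg())
  d <- withr::local_tempdir()
  write_fixture(d, study)
  x <- read_expression(file.path(d, "expression.tsv"),
                       file.path(d, "groups.tsv"),
                       file.path(d, "classes.tsv"))
  expect_identical(x$values, study$expr$values)
  net <- read_edge_list(file.path(d, "ppi_edges.tsv"), min_score = 0)
  expect_identical(net$edges, study$network$edges)
  ann <- read_regulatory(file.path(d, "lnc_mirna.tsv"),
                         file.path(d, "lnc_gene.tsv"),
                         file.path(d, "mirna_gene.tsv"))
  expect_identical(dplyr::arrange(ann$lnc_mirna, lnc_id, mirna_id),
                   dplyr::arrange(study$annotation$lnc_mirna, lnc_id, mirna_id))
  gs <- read_gmt(file.path(d, "gene_sets.gmt"))
  expect_identical(gs$sets, study$genesets$sets)
})
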