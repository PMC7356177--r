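lnc_rec <- function(ids, fcs) {
  rec <- tibble::tibble(
    feature_id = ids, class = "lncRNA",
    log2fc = sign(fcs) * log2(abs(fcs)), fc = fcs,
    p_raw = 1e-6, q_fdr = 1e-5, selected = TRUE
  )
  class(rec) <- c("deg_results", class(rec))
  rec
}

test_that("fold-change gate is inclusive at 4 and keeps strong negatives", {
  rec <- lnc_rec(c("a", "b", "c", "d"), c(-9, 3.9, 4.0, -4.52))
  kept <- filter_by_fc(rec)
  expect_setequal(kept$feature_id, c("a", "c", "d"))
})

test_that("miRNA gate needs at least one validated pair", {
  ann <- regulatory_annotation(
    lnc_mirna = tibble::tibble(l = rep("L1", 29), m = sprintf("miR-%02d", 1:29))
  )
  expect_identical(require_validated_mirnas(c("L1", "L2"), ann), "L1")
  expect_equal(length(resolve_targets("L1", ann, character(0))$targeted_mirnas), 29)
})

test_that("target resolution takes direct and miRNA-mediated genes, DEG-restricted", {
  ann <- regulatory_annotation(
    lnc_mirna = tibble::tibble(l = c("L1", "L1"), m = c("a", "b")),
    lnc_gene = tibble::tibble(l = "L1", g = "g9"),
    mirna_gene = tibble::tibble(m = c("a", "a", "b", "b"),
                                g = c("g1", "g2", "g2", "g3"))
  )
  tg <- resolve_targets("L1", ann, coding_degs = c("g1", "g2"))
  expect_setequal(tg$targeted_mirnas, c("a", "b"))
  expect_setequal(tg$targeted_degs, c("g1", "g2"))  # g9, g3 not DEGs; g2 once

  none <- resolve_targets("L1", regulatory_annotation(), c("g1"))
  expect_equal(length(none$targeted_mirnas), 0)
  expect_equal(length(none$targeted_degs), 0)
})

test_that("records with no DEG targets are excluded", {
  tbl <- candidate_table()
  rec <- as_lnc_priority(tbl)
  kept <- exclude_no_deg_targets(rec)
  expect_equal(nrow(kept), 4)
  expect_false("RP11-283I3.6" %in% kept$lnc_id)
  empty <- rec[0, ]
  expect_equal(nrow(exclude_no_deg_targets(empty)), 0)
})

test_that("module coverage fills labels and associated DEGs consistently", {
  mods <- find_modules(ppi_network(edges = dplyr::bind_rows(
    clique_net(sprintf("x%d", 1:6))$edges,
    clique_net(sprintf("y%d", 1:7))$edges
  )))
  expect_equal(nrow(mods), 2)
  ann <- regulatory_annotation(
    lnc_mirna = tibble::tibble(l = "L1", m = "a"),
    mirna_gene = tibble::tibble(m = c("a", "a", "a"),
                                g = c("x1", "y3", "free"))
  )
  rec <- build_lnc_records(lnc_rec("L1", -6), ann,
                           coding_degs = c("x1", "y3", "free"))
  rec <- module_coverage(rec, mods)
  expect_setequal(rec$module_associated_degs[[1]], c("x1", "y3"))
  expect_setequal(rec$covered_modules[[1]], c("M1", "M2"))
  expect_true(all(lengths(rec$module_associated_degs) <=
                    lengths(rec$targeted_degs)))

  rec2 <- build_lnc_records(lnc_rec("L1", -6), ann, coding_degs = "free")
  rec2 <- module_coverage(rec2, mods)
  expect_equal(length(rec2$covered_modules[[1]]), 0)

  expect_error(module_coverage(rec, mods[0, ]), class = "lncnet_analysis_error")
})

test_that("the published five-candidate table prioritizes exactly two lncRNAs", {
  rec <- as_lnc_priority(candidate_table())
  out <- prioritize_full_coverage(rec, sprintf("M%d", 1:6))
  expect_setequal(out$lnc_id[out$prioritized],
                  c("AC009299.3", "RP11-747H7.3"))
  expect_equal(sum(out$prioritized), 2)
  # covering 5 of 6 modules is not enough
  expect_false(out$prioritized[out$lnc_id == "RP1-151F17.1"])
  # rendered table mirrors the input: "none" for empty sets
  tab <- render_priority_table(out)
  row <- tab[tab$lnc_id == "RP11-283I3.6", ]
  expect_equal(unname(unlist(row[, c("targeted_degs", "module_associated_degs",
                                     "targeted_modules")])),
               c("none", "none", "none"))
})

test_that("cascade filters compose as an intersection and stay monotone", {
  study <- synthesize_study(generator_config(
    n_coding = 400, n_lnc = 80, frac_de = 0.2, module_count = 3,
    module_size = 6, n_driver = 2, seed = 41
  ))
  deg <- select_degs(compute_differential(study$expr))
  sets <- split_by_class(deg)
  mods <- find_modules(induce_deg_network(study$network, sets$coding))
  lnc <- deg[deg$selected & deg$class == "lncRNA", ]
  rec <- prioritize_lncrnas(lnc, study$annotation, sets$coding, mods)

  # each gate's survivors are a subset of the previous gate's
  ids <- rec$lnc_id
  s_fc <- ids[rec$passed_fc]
  s_mirna <- ids[rec$passed_fc & rec$passed_mirna]
  s_deg <- ids[rec$passed_fc & rec$passed_mirna & rec$passed_deg]
  pri <- ids[rec$prioritized]
  expect_true(all(s_mirna %in% s_fc))
  expect_true(all(s_deg %in% s_mirna))
  expect_true(all(pri %in% s_deg))
  # composing in the published order equals intersecting individual passes
  via_filters <- intersect(
    require_validated_mirnas(filter_by_fc(lnc)$feature_id, study$annotation),
    ids[rec$passed_deg]
  )
  expect_setequal(s_deg, via_filters)
  # prioritized implies all pass flags
  expect_true(all(rec$passed_fc[rec$prioritized] &
                    rec$passed_mirna[rec$prioritized] &
                    rec$passed_deg[rec$prioritized]))
})

test_that("synthetic decoys fail exactly at their designed gate", {
  study <- synthesize_study(generator_config(seed = 9))
  deg <- select_degs(compute_differential(study$expr))
  sets <- split_by_class(deg)
  mods <- find_modules(induce_deg_network(study$network, sets$coding))
  lnc <- deg[deg$selected & deg$class == "lncRNA", ]
  rec <- prioritize_lncrnas(lnc, study$annotation, sets$coding, mods)
  dec <- study$truth$decoy_lncs
  row_of <- function(id) rec[rec$lnc_id == id, ]

  r <- row_of(dec[["fc"]])
  expect_false(r$passed_fc); expect_true(r$passed_mirna)
  expect_true(r$passed_deg); expect_false(r$prioritized)

  r <- row_of(dec[["mirna"]])
  expect_true(r$passed_fc); expect_false(r$passed_mirna)
  expect_false(r$prioritized)

  r <- row_of(dec[["deg"]])
  expect_true(r$passed_fc); expect_true(r$passed_mirna)
  expect_false(r$passed_deg); expect_false(r$prioritized)

  r <- row_of(dec[["coverage"]])
  expect_true(r$passed_fc && r$passed_mirna && r$passed_deg)
  expect_equal(length(r$covered_modules[[1]]), nrow(mods) - 1)
  expect_false(r$prioritized)

  expect_setequal(rec$lnc_id[rec$prioritized], study$truth$driver_lncs)
})
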