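test_that("fold-change sign convention and the null case behave", {
  vals <- rbind(
    flat = c(8, 8, 8, 8),        # identical everywhere -> fc = +1
    up = c(10, 10, 8, 8),        # log2fc = 2 -> fc = +4
    down = c(6, 6, 8, 8)         # log2fc = -2 -> fc = -4
  )
  colnames(vals) <- c("A", "B", "C", "D")
  x <- expr_fixture(vals, case = c("A", "B"), control = c("C", "D"))
  res <- suppressMessages(compute_differential(x))
  expect_equal(res$fc[res$feature_id == "flat"], 1)
  expect_equal(res$p_raw[res$feature_id == "flat"], 1)
  expect_equal(res$fc[res$feature_id == "up"], 4)
  expect_equal(res$log2fc[res$feature_id == "up"], 2)
  expect_equal(res$fc[res$feature_id == "down"], -4)
  sel <- select_degs(res)
  expect_false(sel$selected[sel$feature_id == "flat"])
})

test_that("swapping group labels negates log2fc and keeps p-values", {
  withr::local_seed(11)
  vals <- matrix(rnorm(60, 8), nrow = 10,
                 dimnames = list(sprintf("g%02d", 1:10), sprintf("S%d", 1:6)))
  a <- expr_fixture(vals, case = c("S1", "S2", "S3"),
                    control = c("S4", "S5", "S6"))
  b <- expr_fixture(vals, case = c("S4", "S5", "S6"),
                    control = c("S1", "S2", "S3"))
  ra <- compute_differential(a)
  rb <- compute_differential(b)
  expect_equal(ra$log2fc, -rb$log2fc)
  expect_equal(ra$p_raw, rb$p_raw)
})

test_that("selection boundaries are inclusive and idempotent", {
  rec <- tibble::tibble(
    feature_id = c("a", "b", "c", "d"),
    class = "coding",
    log2fc = c(log2(1.5), 0, log2(4.52), log2(1.5)),
    fc = c(1.5, 1, -4.52, 1.5),
    p_raw = c(0.001, 1e-4, 0.001, 0.001),
    q_fdr = c(0.01, 1e-4, 0.001, 0.010001),
    selected = FALSE
  )
  class(rec) <- c("deg_results", class(rec))
  sel <- select_degs(rec)
  expect_true(sel$selected[sel$feature_id == "a"])   # both at the boundary
  expect_false(sel$selected[sel$feature_id == "b"])  # fc = +1
  expect_true(sel$selected[sel$feature_id == "c"])   # strong down-regulation
  expect_false(sel$selected[sel$feature_id == "d"])  # q just above
  expect_identical(select_degs(sel), sel)
  expect_error(select_degs(rec, fc_min = 0.5), class = "lncnet_parameter_error")
})

test_that("a group with fewer than two samples is an analysis error", {
  vals <- matrix(rnorm(9, 8), nrow = 3,
                 dimnames = list(c("a", "b", "c"), c("S1", "S2", "S3")))
  x <- expr_fixture(vals, case = "S1", control = c("S2", "S3"))
  expect_error(compute_differential(x), class = "lncnet_analysis_error")
})

test_that("BH q-values match the brute-force step-up oracle", {
  withr::local_seed(19)
  for (i in 1:50) {
    p <- runif(sample(1:50, 1))
    expect_equal(p.adjust(p, method = "BH"), bh_oracle(p))
  }
  # and on the package's own output
  vals <- matrix(rnorm(200 * 8, 8, 0.5), nrow = 200,
                 dimnames = list(sprintf("g%03d", 1:200), sprintf("S%d", 1:8)))
  x <- expr_fixture(vals, case = sprintf("S%d", 1:4),
                    control = sprintf("S%d", 5:8))
  res <- compute_differential(x)
  expect_equal(res$q_fdr, bh_oracle(res$p_raw))
  expect_true(all(res$q_fdr >= res$p_raw))
})

test_that("class split partitions the selected set", {
  rec <- tibble::tibble(
    feature_id = c("c1", "l1", "c2"),
    class = c("coding", "lncRNA", "coding"),
    log2fc = c(2, 2, 0.1), fc = c(4, 4, 2^0.1),
    p_raw = c(1e-5, 1e-5, 0.5), q_fdr = c(1e-4, 1e-4, 0.6),
    selected = FALSE
  )
  class(rec) <- c("deg_results", class(rec))
  sets <- split_by_class(select_degs(rec))
  expect_identical(sets$coding, "c1")
  expect_identical(sets$lncRNA, "l1")
  expect_identical(deg_ids(select_degs(rec)), c("c1", "l1"))
})

test_that("zero-noise planted DE is recovered exactly at the thresholds", {
  cfg <- generator_config(n_coding = 300, n_lnc = 60, frac_de = 0.1,
                          noise_sd = 0, module_count = 2, module_size = 6,
                          n_driver = 1, seed = 5)
  cohort <- generate_cohort(cfg)
  res <- suppressMessages(select_degs(compute_differential(cohort$expr)))
  planted <- sort(c(cohort$truth$de_up, cohort$truth$de_down))
  expect_identical(sort(deg_ids(res)), planted)
  # noiseless log2fc equals the planted log2 fold change exactly
  fcs <- cohort$truth$planted_fc
  got <- res$fc[match(names(fcs), res$feature_id)]
  expect_equal(got, unname(fcs))
})
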