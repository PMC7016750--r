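test_that("RPKM follows the formula and its invariances", {
  counts <- matrix(c(10, 999990), 2, 1,
                   dimnames = list(c("g1", "g2"), "cave_rep1"))
  lengths <- c(g1 = 1000, g2 = 5000)
  tab <- compute_rpkm(counts, lengths,
                      groups = c(cave_rep1 = "cave"))
  expect_equal(tab$values["g1", 1], 10)

  # gA: 900 / ((2000/1e3) * (1e6/1e6)) = 450; gB: 100 / 0.5 = 200
  counts2 <- matrix(c(900, 100, 999000), 3, 1,
                    dimnames = list(c("gA", "gB", "gC"), "s1"))
  lens2 <- c(gA = 2000, gB = 500, gC = 1000)
  tab2 <- compute_rpkm(counts2, lens2, groups = c(s1 = "cave"))
  expect_equal(unname(tab2$values[c("gA", "gB"), 1]), c(450, 200))

  # uniform per-sample scaling leaves RPKM unchanged
  tab3 <- compute_rpkm(counts2 * 7, lens2, groups = c(s1 = "cave"))
  expect_equal(tab3$values, tab2$values)

  zero <- matrix(0, 1, 1, dimnames = list("g", "bad_sample"))
  expect_error(compute_rpkm(zero, c(g = 100)), "bad_sample")
})

test_that("multi-hit collapse averages contig RPKM per gene", {
  vals <- matrix(c(4, 6, 0, 0, 30, 9), 6, 1,
                 dimnames = list(paste0("c", 1:6), "cave_r1"))
  tab <- expression_table("r", vals, c(cave_r1 = "cave"))
  mapping <- c(c1 = "gX", c2 = "gX", c3 = "gY", c4 = "gY", c5 = "gY")
  out <- collapse_multi_hits(tab, mapping)
  expect_equal(out$values["gX", 1], 5)
  expect_equal(out$values["gY", 1], 10)
  expect_equal(out$values["c6", 1], 9)       # unmapped passes through
  expect_identical(attr(out, "unmapped"), "c6")

  one_to_one <- collapse_multi_hits(tab, setNames(paste0("c", 1:6),
                                                  paste0("c", 1:6)))
  expect_equal(one_to_one$values, tab$values)
})

test_that("fold changes aggregate across references as specified", {
  fcs <- matrix(4, 1, 4, dimnames = list("g1", NULL))
  rec <- fold_changes(tables_from_fc(fcs))
  expect_equal(rec$mean_log2_fc, 2)
  expect_equal(rec$sem_log2_fc, 0)
  expect_equal(rec$sd_statistic, 0)
  expect_identical(rec$direction, "cave_over")

  boundary <- fold_changes(tables_from_fc(
    matrix(c(2, 2, 2, 18), 1, 4, dimnames = list("g1", NULL))))
  expect_equal(boundary$sd_statistic, 8)
  expect_identical(nrow(filter_de(boundary)), 1L)   # sd exactly at the cap

  # zero surface mean: pseudocount keeps the ratio finite and flags it
  vals <- cbind(matrix(5, 1, 3), matrix(0, 1, 3))
  rownames(vals) <- "g1"
  rec0 <- fold_changes(list(toy_table("r1", vals)), pseudocount = 0.1)
  expect_true(is.finite(rec0$fc_r1))
  expect_true(rec0$pseudocount_adjusted)
})

test_that("the DE filter applies all three conditions", {
  under <- fold_changes(tables_from_fc(
    matrix(0.25, 1, 4, dimnames = list("g1", NULL))))
  expect_identical(nrow(filter_de(under)), 1L)

  mixed <- fold_changes(tables_from_fc(
    matrix(c(4, 4, 4, 1.5), 1, 4, dimnames = list("g1", NULL))))
  expect_identical(nrow(filter_de(mixed)), 0L)

  flip <- fold_changes(tables_from_fc(
    matrix(c(4, 4, 4, 0.25), 1, 4, dimnames = list("g1", NULL))))
  expect_identical(nrow(filter_de(flip)), 0L)
})

test_that("filter is monotone in its thresholds", {
  set.seed(42)
  fcs <- matrix(2^rnorm(200 * 4, 0, 2), 200, 4,
                dimnames = list(sprintf("g%03d", 1:200), NULL))
  rec <- fold_changes(tables_from_fc(fcs))
  base <- filter_de(rec, min_fold = 2, max_sd = 8)$gene_id
  stricter_fold <- filter_de(rec, min_fold = 3, max_sd = 8)$gene_id
  stricter_sd <- filter_de(rec, min_fold = 2, max_sd = 4)$gene_id
  expect_true(all(stricter_fold %in% base))
  expect_true(all(stricter_sd %in% base))
})

test_that("noiseless simulated tables are filtered exactly by true effect", {
  eff <- c(gene001 = 4, gene002 = 2, gene003 = 1.5, gene004 = 0.25,
           gene005 = 1)
  cfg <- sim_config(n_genes = 5, replicate_noise_sd = 0,
                    reference_jitter_sd = 0, de_effect_map = eff,
                    rng_seed = 3)
  out <- simulate_expression_tables(cfg)
  kept <- filter_de(fold_changes(out$tables))$gene_id
  expect_setequal(kept, c("gene001", "gene002", "gene004"))
})

test_that("top-gene selection ranks, breaks ties and truncates", {
  rec <- data.frame(
    gene_id = c("gB", "gA", "gC", "gD", "gE"),
    mean_log2_fc = c(3, 3, -5, -1, 2.5),
    direction = c("cave_over", "cave_over", "cave_under", "cave_under",
                  "cave_over"),
    stringsAsFactors = FALSE)
  top <- select_top(rec, n_per_direction = 2)
  expect_identical(top$cave_over$gene_id, c("gA", "gB"))   # tie: lexicographic
  expect_identical(top$cave_under$gene_id, c("gC", "gD"))  # no padding
  expect_identical(nrow(select_top(rec, 50)$cave_over), 3L)
})
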