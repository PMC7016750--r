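test_that("zero-theta filtering removes exactly the affected genes", {
  ts <- matrix(c(0.6, 0.7, 0.5, 0.5, 0.5, 0.5), 2, 3, byrow = TRUE,
               dimnames = list(c("g1", "g2"), NULL))
  tc <- matrix(c(0.4, 0.3, 0.5, 0.5, 0, 0.5), 2, 3, byrow = TRUE,
               dimnames = list(c("g1", "g2"), NULL))
  zf <- filter_zero_theta(theta_df(ts, tc))
  expect_identical(zf$retained, "g1")
  expect_identical(zf$removed$gene_id, "g2")

  clean <- filter_zero_theta(theta_df(ts, abs(1 - ts)))
  expect_identical(nrow(clean$removed), 0L)
})

test_that("intra-allele null has 6 values per gene per allele and mean zero", {
  set.seed(5)
  ts <- matrix(runif(12, 0.3, 0.7), 4, 3,
               dimnames = list(paste0("g", 1:4), NULL))
  est <- theta_df(ts, 1 - ts)
  null_s <- build_intra_allele_null(est, "surface")
  expect_identical(null_s$n, 4L * 6L)
  expect_equal(mean(null_s$values), 0)
  # antisymmetric by construction
  expect_equal(sort(null_s$values), -rev(sort(null_s$values)))

  flat <- theta_df(matrix(0.5, 1, 3, dimnames = list("g", NULL)),
                   matrix(0.5, 1, 3, dimnames = list("g", NULL)))
  expect_true(all(build_intra_allele_null(flat, "cave")$values == 0))

  unordered <- build_intra_allele_null(est, "surface", ordered = FALSE)
  expect_identical(unordered$n, 4L * 3L)

  single <- theta_df(matrix(0.5, 1, 1, dimnames = list("g", NULL)),
                     matrix(0.5, 1, 1, dimnames = list("g", NULL)))
  expect_error(build_intra_allele_null(single, "surface"), "replicates")
})

test_that("merged null ECDF is symmetric: F(x) + F(-x-) = 1", {
  set.seed(6)
  ts <- matrix(runif(30, 0.2, 0.8), 10, 3,
               dimnames = list(sprintf("g%02d", 1:10), NULL))
  est <- theta_df(ts, 1 - ts)
  merged <- merge_nulls(build_intra_allele_null(est, "surface"),
                        build_intra_allele_null(est, "cave"))
  expect_identical(merged$n, 120L)
  f <- ecdf(merged$values)
  # F(x) + F(-x^-) = 1: the left limit excludes the atom at -x
  lhs <- vapply(merged$values, function(x) f(x) + f(-x - 1e-12), numeric(1))
  expect_equal(lhs, rep(1, merged$n), tolerance = 1e-9)
})

test_that("null comparison flags identical and disjoint distributions", {
  n1 <- structure(list(values = c(-1, 0, 1), source = "surface", n = 3L),
                  class = "null_distribution")
  cmp <- compare_nulls(n1, n1)
  expect_equal(cmp$statistic, 0)
  expect_true(cmp$merge_permitted)
  n2 <- structure(list(values = c(10, 20, 30), source = "cave", n = 3L),
                  class = "null_distribution")
  expect_equal(compare_nulls(n1, n2)$statistic, 1)
})

test_that("inter-allele fold changes cover all replicate combinations", {
  lfc <- inter_allele_lfc(c(0.8, 0.8, 0.8), c(0.2, 0.2, 0.2))
  expect_length(lfc, 9)
  expect_equal(lfc, rep(2, 9))
  expect_equal(inter_allele_lfc(rep(0.5, 3), rep(0.5, 3)), rep(0, 9))
  expect_error(inter_allele_lfc(c(0.5, 0), c(0.5, 0.5)), "zero-filter")
})

test_that("K-S statistic matches a brute-force ECDF supremum", {
  expect_equal(ks_two_sample(1:5, 1:5)$statistic, 0)
  expect_equal(ks_two_sample(1:5, 1:5)$p_value, 1)
  expect_equal(ks_two_sample(c(1, 2, 3), c(10, 20, 30))$statistic, 1)
  set.seed(7)
  for (i in 1:20) {
    a <- rnorm(50)
    b <- rnorm(50, mean = runif(1, -1, 1))
    expect_equal(ks_two_sample(a, b)$statistic, oracle_ks_statistic(a, b))
  }
  expect_error(ks_two_sample(numeric(0), 1:3), "non-empty")
})

test_that("exact K-S p-values agree with stats::ks.test without ties", {
  set.seed(8)
  for (i in 1:10) {
    a <- rnorm(sample(3:10, 1))
    b <- rnorm(sample(3:10, 1))
    mine <- ks_two_sample(a, b)
    ref <- suppressWarnings(stats::ks.test(a, b, exact = TRUE))
    expect_equal(mine$statistic, unname(ref$statistic))
    expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-12)
  }
})

test_that("large-sample K-S p uses the asymptotic Kolmogorov distribution", {
  set.seed(9)
  a <- rnorm(200)
  b <- rnorm(300, 0.3)
  mine <- ks_two_sample(a, b)
  expect_false(mine$exact)
  ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-6)
})

test_that("B-H adjustment follows the step-up rule", {
  one <- bh_adjust(0.03)
  expect_equal(one$adjusted, 0.03)
  expect_true(one$significant)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04))$adjusted, rep(0.04, 4))
  expect_false(any(bh_adjust(rep(1, 10))$significant))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  set.seed(10)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    adj <- bh_adjust(p)$adjusted
    expect_equal(adj, p.adjust(p, method = "BH"))
    # order invariance and monotonicity along sorted p
    perm <- sample(seq_along(p))
    expect_equal(bh_adjust(p[perm])$adjusted, adj[perm])
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})

test_that("ASE calls carry nine fold changes and honour the threshold", {
  set.seed(11)
  est <- simulate_theta_estimates(setNames(rep(0.5, 40), sprintf("g%02d", 1:40)),
                                  depth = 500)
  zf <- filter_zero_theta(est)
  merged <- merge_nulls(build_intra_allele_null(zf$estimates, "surface"),
                        build_intra_allele_null(zf$estimates, "cave"))
  calls <- call_ase(zf$estimates, merged)
  expect_identical(ncol(calls[grep("^lfc_", names(calls))]), 9L)
  expect_true(all(calls$significant == (calls$p_adjusted <= 0.05)))
  expect_true(all(diff(abs(calls$mean_lfc)) <= 1e-12))   # sorted by |mean|
  # calls are driven by replicate-coherent imbalance: flagged null genes
  # sit further from zero than unflagged ones
  if (any(calls$significant) && any(!calls$significant)) {
    expect_gt(mean(abs(calls$mean_lfc[calls$significant])),
              mean(abs(calls$mean_lfc[!calls$significant])))
  }
})

test_that("ASE power rises with the true allele imbalance", {
  grid <- c(0.5, 0.65, 0.8)
  power <- vapply(grid, function(th) {
    hits <- 0L
    for (s in 1:8) {
      set.seed(200 + s)
      null_genes <- setNames(rep(0.5, 25), sprintf("n%02d", 1:25))
      test_genes <- setNames(rep(th, 4), sprintf("t%d", 1:4))
      est <- simulate_theta_estimates(c(null_genes, test_genes), depth = 600)
      zf <- filter_zero_theta(est)
      merged <- merge_nulls(build_intra_allele_null(zf$estimates, "surface"),
                            build_intra_allele_null(zf$estimates, "cave"))
      calls <- call_ase(zf$estimates, merged)
      hits <- hits + sum(calls$significant[calls$gene_id %in% names(test_genes)])
    }
    hits / (8 * 4)
  }, numeric(1))
  expect_true(all(diff(power) >= 0))
  expect_gt(power[3], power[1])
})
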