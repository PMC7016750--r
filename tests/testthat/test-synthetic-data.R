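test_that("zero divergence yields identical alleles and no variants", {
  p <- generate_allele_pair("g", 300, 0, rng_seed = 5)
  expect_identical(p$surface_seq, p$cave_seq)
  expect_length(p$variant_sites, 0)
  expect_equal(p$identity, 1)
})

test_that("allele pairs are deterministic and variants match the sequences", {
  p1 <- generate_allele_pair("g", 800, 0.03, rng_seed = 11)
  p2 <- generate_allele_pair("g", 800, 0.03, rng_seed = 11)
  expect_identical(p1, p2)
  s <- strsplit(p1$surface_seq, "")[[1]]
  c_ <- strsplit(p1$cave_seq, "")[[1]]
  expect_identical(which(s != c_), as.integer(p1$variant_sites))
  expect_error(generate_allele_pair("g", 0, 0.1, 1), "positive")
})

test_that("divergence count follows the binomial expectation", {
  h <- vapply(1:500, function(s) {
    length(generate_allele_pair("g", 1000, 0.02, rng_seed = s)$variant_sites)
  }, numeric(1))
  se <- sqrt(1000 * 0.02 * 0.98) / sqrt(500)
  expect_lt(abs(mean(h) - 20), 3 * se)
})

test_that("hybrid read simulation respects theta boundaries and counts", {
  p <- generate_allele_pair("g", 600, 0.02, rng_seed = 2)
  all_surf <- simulate_hybrid_reads(p, 1.0, 500, 100, 250, 30, 0, rng_seed = 3)
  expect_true(all(all_surf$source == "surface"))
  empty <- simulate_hybrid_reads(p, 0.5, 0, 100, 250, 30, 0, rng_seed = 3)
  expect_length(empty$r1, 0)
  half <- simulate_hybrid_reads(p, 0.5, 10000, 100, 250, 30, 0, rng_seed = 4)
  expect_lt(abs(mean(half$source == "surface") - 0.5), 3 * sqrt(0.25 / 10000))
  expect_error(simulate_hybrid_reads(p, 0.5, 10, 700, 250, 30, 0, 1),
               "read_length")
})

test_that("error-free reads match their recorded source allele exactly", {
  p <- generate_allele_pair("g", 500, 0.05, rng_seed = 9)
  rp <- simulate_hybrid_reads(p, 0.5, 200, 80, 200, 25, 0, rng_seed = 10)
  for (k in seq_len(50)) {
    src_seq <- if (rp$source[k] == "surface") p$surface_seq else p$cave_seq
    expect_identical(rp$r1[k], substr(src_seq, rp$start[k], rp$start[k] + 79L))
  }
})

test_that("noiseless expression tables reproduce the true fold change", {
  cfg <- sim_config(n_genes = 5, replicate_noise_sd = 0,
                    reference_jitter_sd = 0,
                    de_effect_map = c(gene002 = 2.0), rng_seed = 21)
  out <- simulate_expression_tables(cfg)
  expect_length(out$tables, 4)
  for (tab in out$tables) {
    cave <- rowMeans(tab$values[, tab$groups == "cave"])
    surf <- rowMeans(tab$values[, tab$groups == "surface"])
    expect_equal(unname(cave["gene002"] / surf["gene002"]), 2.0)
    expect_equal(unname(cave["gene001"] / surf["gene001"]), 1.0)
  }
  out2 <- simulate_expression_tables(cfg)
  expect_identical(out$tables, out2$tables)
})

test_that("null expression tables almost never pass the two-fold filter", {
  cfg <- sim_config(n_genes = 1000, rng_seed = 33)   # all effects 1
  out <- simulate_expression_tables(cfg)
  kept <- filter_de(fold_changes(out$tables))
  expect_lte(nrow(kept) / 1000, 0.01)
})

test_that("generate_study writes a complete, reproducible study", {
  cfg <- sim_config(n_genes = 3, transcript_length = 300, mean_depth = 20,
                    read_length = 50, fragment_length_mean = 120,
                    fragment_length_sd = 15, rng_seed = 8)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- generate_study(cfg, d1)
  m2 <- generate_study(cfg, d2)
  expect_identical(m1$files$md5, m2$files$md5)
  expect_length(grep("_R1\\.fastq$", m1$files$path), 3)
  expect_true(file.exists(file.path(d1, "manifest.json")))

  # empty study is still valid
  d3 <- withr::local_tempdir()
  m3 <- generate_study(sim_config(n_genes = 0, rng_seed = 1), d3)
  expect_true(file.exists(file.path(d3, "alleles.fasta")))
  expect_identical(nrow(read_fasta(file.path(d3, "alleles.fasta"))), 0L)

  # unwritable target (a file in the way) is an I/O error
  blocker <- file.path(withr::local_tempdir(), "blocked")
  file.create(blocker)
  expect_error(generate_study(cfg, blocker), "directory")
})
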