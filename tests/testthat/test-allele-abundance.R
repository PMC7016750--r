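# A minimal two-allele pair with one diagnostic site at position 11.
tiny_pair <- function() {
  surf <- "ACGTACGTAAGTTTACGTAC"
  cave <- "ACGTACGTAACTTTACGTAC"
  structure(list(gene_id = "g", surface_seq = surf, cave_seq = cave,
                 variant_sites = 11L, identity = 0.95,
                 trim_intervals = list(surface = c(0, 20), cave = c(0, 20))),
            class = "allele_pair")
}

test_that("likelihoods follow the mismatch formula at diagnostic sites", {
  p <- tiny_pair()
  e <- 0.01
  read <- substr(p$surface_seq, 6, 15)          # spans the diagnostic site
  ll <- read_allele_likelihood(read, read, p, error_rate = e)
  # both mates identical: 0 vs 1 mismatch per mate
  expect_equal(unname(ll[1, "surface"] - ll[1, "cave"]),
               2 * (log(1 - e) - log(e / 3)))

  off_site <- substr(p$surface_seq, 1, 8)       # no diagnostic site
  ll2 <- read_allele_likelihood(off_site, off_site, p, error_rate = e)
  expect_equal(ll2[1, "surface"], ll2[1, "cave"])

  n_read <- read
  substr(n_read, 6, 6) <- "N"                   # N at the diagnostic site
  ll3 <- read_allele_likelihood(n_read, off_site, p, error_rate = e)
  expect_equal(ll3[1, "surface"], ll3[1, "cave"])

  # reverse-complement reads align equally well
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  ll4 <- read_allele_likelihood(rc, rc, p, error_rate = e)
  expect_equal(ll4, ll, ignore_attr = TRUE)
})

test_that("score gate discards unalignable junk and reports it", {
  p <- tiny_pair()
  junk <- strrep("A", 20)
  ll <- read_allele_likelihood(c(junk, substr(p$surface_seq, 1, 10)),
                               c(junk, substr(p$surface_seq, 11, 20)), p)
  expect_identical(attr(ll, "n_discarded"), 1L)
  expect_identical(nrow(ll), 1L)
})

test_that("the capped pair scorer agrees with the exhaustive scanner", {
  p <- generate_allele_pair("g", 500, 0.02, rng_seed = 21)
  rp <- simulate_hybrid_reads(p, 0.5, 150, 100, 250, 30, 0.01, rng_seed = 22)
  cap <- as.integer(ceiling(0.1 * 200))
  fast <- hybridase:::pair_allele_mismatches(rp$r1, rp$r2, p$surface_seq,
                                             p$cave_seq, cap)
  slow_s <- hybridase:::align_reads_ungapped(rp$r1, p$surface_seq) +
    hybridase:::align_reads_ungapped(rp$r2, p$surface_seq)
  slow_c <- hybridase:::align_reads_ungapped(rp$r1, p$cave_seq) +
    hybridase:::align_reads_ungapped(rp$r2, p$cave_seq)
  # exact wherever the exhaustive count is within the per-mate clamp
  ok <- slow_s <= cap & slow_c <= cap
  expect_gt(mean(ok), 0.95)
  expect_identical(fast[ok, "surface"], slow_s[ok])
  expect_identical(fast[ok, "cave"], slow_c[ok])
})

test_that("EM recovers boundary and symmetric thetas", {
  p <- generate_allele_pair("g", 400, 0.05, rng_seed = 31)
  rp <- simulate_hybrid_reads(p, 1.0, 300, 80, 200, 25, 0, rng_seed = 32)
  est <- estimate_theta(rp, p, error_rate = 0.005, prior_pseudocount = 1e-9,
                        fragment_mean = 200)
  expect_gt(est$theta[["surface"]], 0.999)

  ident <- generate_allele_pair("g", 400, 0, rng_seed = 31)
  rp0 <- simulate_hybrid_reads(ident, 0.7, 200, 80, 200, 25, 0, rng_seed = 33)
  est0 <- estimate_theta(rp0, ident, fragment_mean = 200)
  expect_identical(unname(est0$theta), c(0.5, 0.5))

  none <- estimate_theta(list(r1 = character(0), r2 = character(0)), p)
  expect_false(none$defined)
  expect_true(is.na(none$theta[["surface"]]))
})

test_that("EM is label-swap equivariant and its likelihood never decreases", {
  p <- generate_allele_pair("g", 500, 0.02, rng_seed = 41)
  rp <- simulate_hybrid_reads(p, 0.65, 400, 100, 250, 30, 0.005, rng_seed = 42)
  est <- estimate_theta(rp, p, fragment_mean = 250)
  swapped <- p
  swapped$surface_seq <- p$cave_seq
  swapped$cave_seq <- p$surface_seq
  est_sw <- estimate_theta(rp, swapped, fragment_mean = 250)
  expect_equal(unname(est$theta[["surface"]]), unname(est_sw$theta[["cave"]]))
  expect_true(all(diff(est$loglik) >= -1e-8))
  expect_true(est$converged)
  expect_equal(sum(est$theta), 1, tolerance = 1e-9)
  expect_equal(sum(est$expected_fragments), est$n_retained)
})

test_that("theta recovery is unbiased at zero sequencing error", {
  errs <- vapply(1:6, function(s) {
    p <- generate_allele_pair("g", 500, 0.02, rng_seed = 50 + s)
    rp <- simulate_hybrid_reads(p, 0.6, 500, 100, 250, 30, 0, rng_seed = 60 + s)
    est <- estimate_theta(rp, p, error_rate = 0.005, fragment_mean = 250)
    est$theta[["surface"]] - mean(rp$source == "surface")
  }, numeric(1))
  # estimate tracks the realized allele fraction to well within binomial noise
  expect_lt(max(abs(errs)), 3 * sqrt(0.25 / 500))
})

test_that("study-level estimation returns tidy per-replicate thetas", {
  pairs <- lapply(1:2, function(g) {
    generate_allele_pair(sprintf("gene%03d", g), 400, 0.03, rng_seed = 70 + g)
  })
  names(pairs) <- vapply(pairs, `[[`, character(1), "gene_id")
  reps <- lapply(1:2, function(r) {
    rps <- lapply(pairs, function(p) {
      simulate_hybrid_reads(p, 0.5, 100, 80, 200, 25, 0.005,
                            rng_seed = 100 * r + match(p$gene_id, names(pairs)))
    })
    list(r1 = unlist(lapply(rps, `[[`, "r1")),
         r2 = unlist(lapply(rps, `[[`, "r2")),
         id = unlist(lapply(names(pairs), function(g)
           sprintf("%s:rep%d:%d", g, r, seq_len(100)))))
  })
  df <- estimate_theta_study(pairs, reps, fragment_mean = 200)
  expect_identical(nrow(df), 2L * 2L * 2L)   # gene x allele x replicate
  sums <- tapply(df$theta, interaction(df$gene_id, df$replicate), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})
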