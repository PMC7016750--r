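# Shared fixture builders. Everything is generated in code; nothing on disk.

# A small expression_table with explicit values.
toy_table <- function(reference_id, values, n_rep = 3) {
  genes <- rownames(values)
  samples <- c(sprintf("cave_rep%d", seq_len(n_rep)),
               sprintf("surface_rep%d", seq_len(n_rep)))
  stopifnot(ncol(values) == 2 * n_rep)
  colnames(values) <- samples
  expression_table(reference_id, values,
                   stats::setNames(rep(c("cave", "surface"), each = n_rep),
                                   samples))
}

# Four-reference tables in which each gene has a constant cave/surface ratio
# per reference (no replicate noise): fc_matrix is genes x 4 of linear FCs.
tables_from_fc <- function(fc_matrix, surface_level = 10) {
  lapply(seq_len(ncol(fc_matrix)), function(r) {
    vals <- cbind(matrix(rep(surface_level * fc_matrix[, r], 3), ncol = 3),
                  matrix(surface_level, nrow(fc_matrix), 3))
    rownames(vals) <- rownames(fc_matrix)
    toy_table(sprintf("ref%d", r), vals)
  })
}

# Theta-estimate data frame from a matrix of thetas:
# rows = genes, columns = surface reps then cave reps.
theta_df <- function(theta_surface, theta_cave) {
  stopifnot(nrow(theta_surface) == nrow(theta_cave))
  genes <- rownames(theta_surface)
  n_rep <- ncol(theta_surface)
  do.call(rbind, lapply(seq_along(genes), function(g) {
    data.frame(
      gene_id = genes[g],
      allele = rep(c("surface", "cave"), each = n_rep),
      replicate = rep(seq_len(n_rep), 2),
      expected_fragments = NA_real_, fpkm = NA_real_,
      theta = c(theta_surface[g, ], theta_cave[g, ]),
      defined = TRUE, stringsAsFactors = FALSE)
  }))
}

# Binomial-noise theta estimates: theta_hat = X / depth per replicate,
# mirroring read-count sampling noise without simulating reads. Values of
# exactly 0/1 are nudged inside (0,1) like a pseudocounted estimate.
simulate_theta_estimates <- function(genes_theta, n_rep = 3, depth = 600) {
  n <- length(genes_theta)
  draw <- function(th) {
    x <- stats::rbinom(n_rep, depth, th)
    pmin(pmax(x / depth, 0.5 / depth), 1 - 0.5 / depth)
  }
  ts <- t(vapply(genes_theta, draw, numeric(n_rep)))
  tc <- 1 - ts
  rownames(ts) <- rownames(tc) <- names(genes_theta)
  theta_df(ts, tc)
}

# Brute-force K-S statistic: supremum of |ECDF difference| over all pooled
# points, computed from first principles (independent of the package).
oracle_ks_statistic <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  fa <- vapply(pts, function(x) mean(a <= x), numeric(1))
  fb <- vapply(pts, function(x) mean(b <= x), numeric(1))
  max(abs(fa - fb))
}

# Exhaustive permutation oracle for the exact two-sample K-S p-value:
# enumerate every assignment of the pooled values to the two samples.
oracle_ks_exact_p <- function(a, b) {
  n <- length(a)
  pooled <- c(a, b)
  d_obs <- oracle_ks_statistic(a, b)
  combos <- utils::combn(length(pooled), n)
  stats_perm <- apply(combos, 2, function(idx) {
    oracle_ks_statistic(pooled[idx], pooled[-idx])
  })
  mean(stats_perm >= d_obs - 1e-12)
}
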