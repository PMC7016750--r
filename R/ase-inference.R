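#' Remove genes with any zero (or undefined) THETA
#'
#' A gene is removed iff any of its `2 x n_replicates` theta values is zero,
#' `NA`, or flagged undefined.
#'
#' @param estimates theta data frame from [estimate_theta_study()].
#' @return list with `estimates` (retained rows), `retained` (gene IDs) and
#'   `removed` (data frame gene_id, reason).
#' @export
filter_zero_theta <- function(estimates) {
  def <- if (is.null(estimates$defined)) TRUE else estimates$defined
  bad <- is.na(estimates$theta) | !def
  bad <- bad | (!is.na(estimates$theta) & estimates$theta == 0)
  removed_genes <- unique(estimates$gene_id[bad])
  retained <- setdiff(unique(estimates$gene_id), removed_genes)
  list(
    estimates = estimates[!(estimates$gene_id %in% removed_genes), ,
                          drop = FALSE],
    retained = retained,
    removed = data.frame(gene_id = removed_genes,
                         reason = rep("zero or undefined theta",
                                      length(removed_genes)),
                         stringsAsFactors = FALSE)
  )
}

#' Intra-allele null distribution of replicate log fold changes
#'
#' For each gene, appends `log2(theta_i / theta_j)` for every ordered
#' replicate pair (i != j) within the given allele. Both orderings are
#' included, so the pooled null is symmetric about zero by construction.
#'
#' @param estimates zero-filtered theta data frame.
#' @param allele `"surface"` or `"cave"`.
#' @param ordered include both orderings (default) or only i < j.
#' @return object of class `null_distribution`: list with `values`,
#'   `source`, `n`.
#' @export
build_intra_allele_null <- function(estimates, allele = c("surface", "cave"),
                                    ordered = TRUE) {
  allele <- match.arg(allele)
  sub <- estimates[estimates$allele == allele, , drop = FALSE]
  vals <- unlist(lapply(split(sub$theta, sub$gene_id), function(th) {
    if (length(th) < 2L) stop("need >= 2 replicates per allele")
    idx <- expand.grid(i = seq_along(th), j = seq_along(th))
    idx <- idx[idx$i != idx$j, , drop = FALSE]
    if (!ordered) idx <- idx[idx$i < idx$j, , drop = FALSE]
    log2(th[idx$i] / th[idx$j])
  }), use.names = FALSE)
  if (is.null(vals)) vals <- numeric(0)
  structure(list(values = vals, source = allele, n = length(vals)),
            class = "null_distribution")
}

#' Merge per-allele null distributions
#' @param surface_null,cave_null `null_distribution` objects.
#' @return merged `null_distribution` (`source = "merged"`).
#' @export
merge_nulls <- function(surface_null, cave_null) {
  structure(list(values = c(surface_null$values, cave_null$values),
                 source = "merged",
                 n = surface_null$n + cave_null$n),
            class = "null_distribution")
}

#' Compare the surface and cave null distributions
#'
#' Two-sample K-S test between the per-allele nulls, with a merge-permitted
#' flag (p above `gate`). Merging is always allowed to proceed; the flag is
#' reported so a caller can inspect distinguishable nulls.
#'
#' @param surface_null,cave_null `null_distribution` objects.
#' @param gate p-value threshold for the flag.
#' @return list with `statistic`, `p_value`, `merge_permitted`.
#' @export
compare_nulls <- function(surface_null, cave_null, gate = 0.05) {
  ks <- ks_two_sample(surface_null$values, cave_null$values)
  list(statistic = ks$statistic, p_value = ks$p_value,
       merge_permitted = ks$p_value > gate)
}

#' Inter-allele log2 fold changes for one gene
#'
#' `log2(theta_surface_i / theta_cave_j)` for every replicate combination:
#' with three replicates per allele, nine values.
#'
#' @param theta_surface,theta_cave per-replicate theta values (> 0).
#' @return numeric vector of length `n_surface * n_cave`.
#' @export
inter_allele_lfc <- function(theta_surface, theta_cave) {
  if (any(theta_surface <= 0) || any(theta_cave <= 0))
    stop("zero theta reached inter_allele_lfc; zero-filter contract violated")
  as.vector(outer(theta_surface, theta_cave, function(s, c_) log2(s / c_)))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' The statistic is the supremum of `|ECDF_a - ECDF_b|`, with both ECDFs
#' evaluated at the pooled sorted points (so ties are handled by
#' construction). The p-value is exact — the permutation probability of a
#' statistic at least as large, over all equally likely assignments of the
#' pooled values to the two samples, computed by lattice counting
#' conditional on the observed tie pattern — when `min(n_a, n_b) <= 25`,
#' and otherwise uses the asymptotic Kolmogorov distribution with the
#' standard effective size `n_a n_b / (n_a + n_b)`.
#'
#' @param a,b numeric samples (non-empty, finite).
#' @return list with `statistic`, `p_value`, `exact` (logical).
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("samples must be non-empty")
  if (anyNA(a) || anyNA(b) || any(!is.finite(c(a, b))))
    stop("samples must be finite")
  n <- length(a); m <- length(b)
  d <- ks_statistic(a, b)
  exact <- min(n, m) <= 25L
  p <- if (exact) ks_exact_p(a, b, d) else ks_asymptotic_p(d, n, m)
  list(statistic = d, p_value = p, exact = exact)
}

# sup |ECDF_a - ECDF_b| over the distinct pooled points
ks_statistic <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  ea <- stats::ecdf(a)(pts)
  eb <- stats::ecdf(b)(pts)
  max(abs(ea - eb))
}

# Exact permutation p-value by lattice-path counting over tie groups.
# Scaled to integers: D = |m*i - n*j| / (n*m), so the boundary test is
# exact. Counts assignments whose maximum D stays strictly below the
# observed one; p = 1 - good / choose(n+m, n).
ks_exact_p <- function(a, b, d_obs) {
  n <- length(a); m <- length(b)
  sizes <- as.vector(table(c(a, b)))        # tie-group sizes, sorted values
  d_int <- as.integer(round(d_obs * n * m))
  if (d_int <= 0L) return(1)
  # w[i+1] = weighted number of partial assignments with i a's placed
  w <- c(1, rep(0, n))
  t_done <- 0L
  for (cg in sizes) {
    new_w <- rep(0, n + 1L)
    for (i_prev in which(w > 0) - 1L) {
      b_prev <- t_done - i_prev
      kmax <- min(cg, n - i_prev)
      for (k in 0:kmax) {
        if (cg - k > m - b_prev) next
        new_w[i_prev + k + 1L] <- new_w[i_prev + k + 1L] +
          w[i_prev + 1L] * choose(cg, k)
      }
    }
    t_done <- t_done + cg
    # boundary check at the end of each distinct value
    i_all <- 0:n
    viol <- abs(m * i_all - n * (t_done - i_all)) >= d_int
    new_w[viol] <- 0
    w <- new_w
  }
  good <- w[n + 1L]
  1 - good / choose(n + m, n)
}

# Asymptotic two-sided p from the Kolmogorov distribution
ks_asymptotic_p <- function(d, n, m) {
  ne <- n * m / (n + m)
  lambda <- sqrt(ne) * d
  if (lambda == 0) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Sorts the p-values ascending and sets `adjusted_i = min over j >= i of
#' (m * p_j / j)`, clipped at 1; significance is `adjusted <= alpha`.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @param alpha FDR level.
#' @return list with `adjusted` (input order) and `significant` (logical).
#' @export
bh_adjust <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0L)
    return(list(adjusted = numeric(0), significant = logical(0)))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must be in [0, 1]")
  m <- length(p_values)
  ord <- order(p_values)
  ranked <- p_values[ord]
  adj_sorted <- rev(cummin(rev(m * ranked / seq_len(m))))
  adj_sorted <- pmin(adj_sorted, 1)
  adjusted <- numeric(m)
  adjusted[ord] <- adj_sorted
  list(adjusted = adjusted, significant = adjusted <= alpha)
}

#' Call allele-specific expression against the merged null
#'
#' Per gene: the inter-allele log2 fold changes (all surface x cave
#' replicate combinations) are tested against the pooled intra-allele null
#' with [ks_two_sample()]; p-values are B-H adjusted across all tested
#' genes. Direction is the sign of the mean inter-allele log2 fold change
#' (positive = surface_biased).
#'
#' @param estimates zero-filtered theta data frame.
#' @param null merged `null_distribution`.
#' @param alpha FDR level.
#' @return data frame sorted by `|mean_lfc|` descending: `gene_id`,
#'   `lfc_1..k`, `ks_statistic`, `p_value`, `p_adjusted`, `significant`,
#'   `direction`, `mean_lfc`, `sem_lfc`.
#' @export
call_ase <- function(estimates, null, alpha = 0.05) {
  genes <- unique(estimates$gene_id)
  lfcs <- lapply(genes, function(g) {
    sub <- estimates[estimates$gene_id == g, , drop = FALSE]
    inter_allele_lfc(sub$theta[sub$allele == "surface"],
                     sub$theta[sub$allele == "cave"])
  })
  k <- if (length(lfcs)) length(lfcs[[1]]) else 0L
  ks <- lapply(lfcs, function(v) ks_two_sample(v, null$values))
  p <- vapply(ks, `[[`, numeric(1), "p_value")
  adj <- bh_adjust(p, alpha)
  mean_lfc <- vapply(lfcs, mean, numeric(1))
  sem_lfc <- vapply(lfcs, function(v) stats::sd(v) / sqrt(length(v)),
                    numeric(1))
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  if (k > 0L) {
    lfc_mat <- do.call(rbind, lfcs)
    colnames(lfc_mat) <- paste0("lfc_", seq_len(k))
    out <- cbind(out, as.data.frame(lfc_mat))
  }
  out$ks_statistic <- vapply(ks, `[[`, numeric(1), "statistic")
  out$p_value <- p
  out$p_adjusted <- adj$adjusted
  out$significant <- adj$significant
  out$direction <- ifelse(mean_lfc >= 0, "surface_biased", "cave_biased")
  out$mean_lfc <- mean_lfc
  out$sem_lfc <- sem_lfc
  out <- out[order(-abs(out$mean_lfc)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
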