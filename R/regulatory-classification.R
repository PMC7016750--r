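#' Classify one gene's regulatory pattern from DE and ASE
#'
#' In an F1 hybrid both alleles share one trans-regulatory environment, so
#' population-level differential expression (DE) that is mirrored by
#' allele-biased expression in the hybrid points to a cis-regulatory change,
#' while DE without ASE is consistent with a trans change (tissue dilution
#' means cis-regulation cannot be excluded for such genes). Significant ASE
#' opposing the DE direction suggests competing cis-by-trans effects.
#' Parent-of-origin effects are not distinguishable from cis effects in a
#' single cross direction.
#'
#' @param de_direction `"cave_over"` or `"cave_under"` (DE of cave relative
#'   to surface).
#' @param ase_significant logical.
#' @param ase_direction `"surface_biased"` or `"cave_biased"`.
#' @return one of `"cis_concordant"`, `"trans_consistent"`,
#'   `"discordant_cis_by_trans"`.
#' @export
classify <- function(de_direction, ase_significant, ase_direction) {
  stopifnot(de_direction %in% c("cave_over", "cave_under"),
            ase_direction %in% c("surface_biased", "cave_biased"))
  if (!ase_significant) return("trans_consistent")
  concordant <- (de_direction == "cave_under" &&
                   ase_direction == "surface_biased") ||
    (de_direction == "cave_over" && ase_direction == "cave_biased")
  if (concordant) "cis_concordant" else "discordant_cis_by_trans"
}

#' Combine DE records and ASE calls into regulatory calls
#'
#' Genes present in only one of the two inputs are skipped and listed in
#' the `skipped` attribute.
#'
#' @param de_records fold-change records ([fold_changes()] /
#'   [filter_de()]).
#' @param ase_calls output of [call_ase()].
#' @return data frame: `gene_id`, `de_direction`, `de_mean_lfc`,
#'   `de_sem_lfc`, `ase_significant`, `ase_direction`, `ase_mean_lfc`,
#'   `ase_sem_lfc`, `category`; attribute `skipped`.
#' @export
classify_genes <- function(de_records, ase_calls) {
  shared <- intersect(de_records$gene_id, ase_calls$gene_id)
  skipped <- setdiff(union(de_records$gene_id, ase_calls$gene_id), shared)
  de <- de_records[match(shared, de_records$gene_id), , drop = FALSE]
  ase <- ase_calls[match(shared, ase_calls$gene_id), , drop = FALSE]
  out <- data.frame(
    gene_id = shared,
    de_direction = de$direction,
    de_mean_lfc = de$mean_log2_fc,
    de_sem_lfc = de$sem_log2_fc,
    ase_significant = ase$significant,
    ase_direction = ase$direction,
    ase_mean_lfc = ase$mean_lfc,
    ase_sem_lfc = ase$sem_lfc,
    stringsAsFactors = FALSE
  )
  out$category <- mapply(classify, out$de_direction, out$ase_significant,
                         out$ase_direction)
  attr(out, "skipped") <- skipped
  out
}

#' DE/ASE concordance tallies per DE direction
#'
#' Among significant-ASE genes, counts how many are concordant (ASE favors
#' the same population as DE) out of the total in each DE direction.
#'
#' @param calls output of [classify_genes()].
#' @return data frame with rows `cave_under` (surface-favored DE) and
#'   `cave_over`: columns `n_concordant`, `n_total`.
#' @export
concordance_counts <- function(calls) {
  sig <- calls[calls$ase_significant, , drop = FALSE]
  tally <- function(dir) {
    sub <- sig[sig$de_direction == dir, , drop = FALSE]
    c(n_concordant = sum(sub$category == "cis_concordant"),
      n_total = nrow(sub))
  }
  out <- rbind(cave_under = tally("cave_under"),
               cave_over = tally("cave_over"))
  as.data.frame(out)
}

#' Spearman correlation between DE and ASE fold changes
#'
#' Rank-transforms both vectors (average ranks for ties), computes the
#' Pearson correlation of the ranks, and a p-value from the t
#' approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom (two-sided).
#'
#' @param de_lfcs,ase_lfcs paired numeric vectors (n >= 3).
#' @return list with `rho`, `p_value`, `n`.
#' @export
spearman_de_vs_ase <- function(de_lfcs, ase_lfcs) {
  n <- length(de_lfcs)
  if (n != length(ase_lfcs)) stop("inputs must be paired")
  if (n < 3L) stop("need at least 3 pairs")
  rho <- stats::cor(rank(de_lfcs), rank(ase_lfcs))
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}
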