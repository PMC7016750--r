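#' RPKM normalization of a count matrix
#'
#' `RPKM[g, s] = counts[g, s] / ((length[g] / 1e3) * (total_mapped[s] / 1e6))`
#' with `total_mapped[s]` the column sum of the counts.
#'
#' @param counts gene x sample read-count matrix (dimnames required).
#' @param lengths named vector of transcript lengths in bases (> 0),
#'   covering every gene in `counts`.
#' @param reference_id label for the resulting table.
#' @param groups named sample-group vector (see [expression_table()]);
#'   inferred from sample-ID prefixes when `NULL`.
#' @return an `expression_table` of RPKM values.
#' @export
compute_rpkm <- function(counts, lengths, reference_id = "ref",
                         groups = NULL) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  if (any(counts < 0)) stop("counts must be >= 0")
  lengths <- lengths[rownames(counts)]
  if (anyNA(lengths) || any(lengths <= 0))
    stop("every gene needs a positive length")
  totals <- colSums(counts)
  if (any(totals == 0))
    stop("sample(s) with zero mapped reads: ",
         paste(colnames(counts)[totals == 0], collapse = ", "))
  rpkm <- sweep(counts / (lengths / 1e3), 2, totals / 1e6, "/")
  if (is.null(groups))
    groups <- stats::setNames(sub("_.*$", "", colnames(counts)),
                              colnames(counts))
  expression_table(reference_id, rpkm, groups)
}

#' Average RPKM over contigs hitting the same reference gene
#'
#' Per gene and sample, the output RPKM is the arithmetic mean of the RPKM
#' of its contigs. Contigs absent from the mapping pass through unchanged
#' under their own ID (recorded in the `unmapped` attribute).
#'
#' @param table an `expression_table` whose rows are contigs.
#' @param contig_to_gene named character vector, contig ID -> gene ID.
#' @return an `expression_table` with one row per gene; attribute `unmapped`
#'   lists pass-through contigs.
#' @export
collapse_multi_hits <- function(table, contig_to_gene) {
  contigs <- rownames(table$values)
  gene <- unname(contig_to_gene[contigs])
  unmapped <- contigs[is.na(gene)]
  gene[is.na(gene)] <- contigs[is.na(gene)]
  agg <- rowsum(table$values, group = gene) /
    as.vector(table(gene)[sort(unique(gene))])
  out <- expression_table(table$reference_id,
                          agg[sort(unique(gene)), , drop = FALSE],
                          table$groups)
  attr(out, "unmapped") <- unmapped
  out
}

#' Per-reference cave/surface fold changes
#'
#' For each reference, group means are the arithmetic means of replicate
#' RPKM; the linear fold change is `cave_mean / surface_mean`. When either
#' group mean is zero the pseudocount `eps` is added to both means of that
#' gene (in every reference) to keep the ratio finite, and the record is
#' flagged `pseudocount_adjusted`. Across references the record carries the
#' mean log2 fold change, its SEM, and `sd_statistic` — the sample standard
#' deviation of the per-reference linear fold changes.
#'
#' @param tables list of `expression_table`s, one per reference.
#' @param pseudocount RPKM added to both group means before the ratio.
#' @return data frame with one row per gene: per-reference linear fold
#'   changes (`fc_<ref>`), `mean_log2_fc`, `sem_log2_fc`, `sd_statistic`,
#'   `direction` (`cave_over`/`cave_under`, by the mean log2 fold change),
#'   `complete` (present in every reference), `pseudocount_adjusted`.
#' @export
fold_changes <- function(tables, pseudocount = 0.1) {
  stopifnot(length(tables) >= 1L)
  refs <- vapply(tables, `[[`, character(1), "reference_id")
  genes <- sort(unique(unlist(lapply(tables, function(t) rownames(t$values)))))
  cave_means <- surf_means <- matrix(NA_real_, length(genes), length(tables),
                                     dimnames = list(genes, refs))
  for (r in seq_along(tables)) {
    tab <- tables[[r]]
    cave <- tab$values[, tab$groups == "cave", drop = FALSE]
    surf <- tab$values[, tab$groups == "surface", drop = FALSE]
    if (ncol(cave) == 0L || ncol(surf) == 0L)
      stop("reference ", refs[r], " lacks a cave or surface group")
    idx <- match(rownames(tab$values), genes)
    cave_means[idx, r] <- rowMeans(cave)
    surf_means[idx, r] <- rowMeans(surf)
  }
  adjusted <- apply(cave_means == 0 | surf_means == 0, 1, any)
  adjusted[is.na(adjusted)] <- FALSE
  eps <- ifelse(adjusted, pseudocount, 0)
  fc <- (cave_means + eps) / (surf_means + eps)
  lfc <- log2(fc)
  mean_lfc <- rowMeans(lfc)
  sem <- apply(lfc, 1, stats::sd) / sqrt(ncol(lfc))
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (r in seq_along(refs)) out[[paste0("fc_", refs[r])]] <- fc[, r]
  out$mean_log2_fc <- mean_lfc
  out$sem_log2_fc <- sem
  out$sd_statistic <- apply(fc, 1, stats::sd)
  out$direction <- ifelse(mean_lfc >= 0, "cave_over", "cave_under")
  out$complete <- rowSums(is.na(fc)) == 0L
  out$pseudocount_adjusted <- adjusted
  rownames(out) <- NULL
  out
}

fc_columns <- function(records) {
  grep("^fc_", names(records), value = TRUE)
}

#' Multi-reference differential-expression filter
#'
#' Retains a gene iff its linear fold change is at least `min_fold`-fold in
#' the same direction (ratio `>= min_fold` or `<= 1/min_fold`) in every
#' reference, and the standard deviation of the per-reference linear fold
#' changes is at most `max_sd`. Records missing any reference are dropped.
#'
#' @param records output of [fold_changes()].
#' @param min_fold minimum linear fold change (default two-fold).
#' @param max_sd maximum `sd_statistic`.
#' @return the retained subset of `records`.
#' @export
filter_de <- function(records, min_fold = 2, max_sd = 8) {
  fc <- as.matrix(records[, fc_columns(records), drop = FALSE])
  up <- rowSums(fc >= min_fold) == ncol(fc)
  down <- rowSums(fc <= 1 / min_fold) == ncol(fc)
  keep <- records$complete & (up | down) & records$sd_statistic <= max_sd
  keep[is.na(keep)] <- FALSE
  records[keep, , drop = FALSE]
}

#' Top genes per direction by fold-change magnitude
#'
#' Ranks filtered records by `|mean_log2_fc|` descending within each
#' direction (ties broken by gene ID) and returns up to `n_per_direction`
#' from each.
#'
#' @param records filtered fold-change records.
#' @param n_per_direction list length cap per direction.
#' @return list with `cave_under` and `cave_over` data frames (ranked).
#' @export
select_top <- function(records, n_per_direction = 50) {
  pick <- function(dir) {
    sub <- records[records$direction == dir, , drop = FALSE]
    ord <- order(-abs(sub$mean_log2_fc), sub$gene_id)
    sub <- sub[ord, , drop = FALSE]
    utils::head(sub, n_per_direction)
  }
  list(cave_under = pick("cave_under"), cave_over = pick("cave_over"))
}
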