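#' Pipeline configuration
#'
#' Collects every stage parameter and the input/output paths. Defaults
#' follow the study design the pipeline models: four reference
#' transcriptomes, three hybrid replicates, a two-fold/-SD-8 DE filter,
#' top 50 genes per direction, and B-H FDR at 0.05.
#'
#' @param study_dir directory with the study inputs (allele FASTA, hybrid
#'   FASTQ pairs, expression tables) — written there by [run_simulate()].
#' @param output_dir directory for stage outputs.
#' @param sim a [sim_config()] used by [run_simulate()].
#' @param min_fold,max_sd,top_n DE filter and selection parameters.
#' @param min_identity allele-pair trimming acceptance threshold.
#' @param error_rate,max_mismatch_rate,prior_pseudocount,tol,max_iter
#'   THETA estimation parameters.
#' @param alpha B-H FDR level.
#' @param null_ordered_pairs use both orderings of each replicate pair in
#'   the intra-allele null.
#' @param correlation_gene_set `"significant"` (significant-ASE genes) or
#'   `"all"` tested genes for the DE-vs-ASE correlation.
#' @param rng_seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(study_dir, output_dir,
                            sim = sim_config(),
                            min_fold = 2, max_sd = 8, top_n = 50,
                            min_identity = 0.90,
                            error_rate = 0.005, max_mismatch_rate = 0.1,
                            prior_pseudocount = 1.0, tol = 1e-6,
                            max_iter = 500L, alpha = 0.05,
                            null_ordered_pairs = TRUE,
                            correlation_gene_set = c("significant", "all"),
                            rng_seed = 1L) {
  structure(list(
    study_dir = study_dir, output_dir = output_dir, sim = sim,
    min_fold = min_fold, max_sd = max_sd, top_n = top_n,
    min_identity = min_identity, error_rate = error_rate,
    max_mismatch_rate = max_mismatch_rate,
    prior_pseudocount = prior_pseudocount, tol = tol, max_iter = max_iter,
    alpha = alpha, null_ordered_pairs = null_ordered_pairs,
    correlation_gene_set = match.arg(correlation_gene_set),
    rng_seed = as.integer(rng_seed)),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a `sim` block
#' mirrors [sim_config()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  sim_args <- y$sim
  if (!is.null(sim_args$theta_map)) sim_args$theta_map <- unlist(sim_args$theta_map)
  if (!is.null(sim_args$de_effect_map)) sim_args$de_effect_map <- unlist(sim_args$de_effect_map)
  y$sim <- do.call(sim_config, as.list(sim_args))
  do.call(pipeline_config, y)
}

need_file <- function(path, hint) {
  if (!file.exists(path))
    stop("missing input: ", path, " (", hint, ")")
  path
}

#' Run the simulation stage
#' @param config a `pipeline_config`.
#' @return the study manifest, invisibly.
#' @export
run_simulate <- function(config) {
  generate_study(config$sim, config$study_dir)
}

#' Run the differential-expression stage
#'
#' Reads the per-reference expression tables from the study directory,
#' computes per-reference fold changes, applies the multi-reference filter
#' and selects the top genes per direction.
#'
#' @param config a `pipeline_config`.
#' @return list with `records`, `filtered`, `top`; writes
#'   `fold_changes.tsv`, `de_filtered.tsv`, `top_cave_under.tsv`,
#'   `top_cave_over.tsv` under `output_dir`.
#' @export
run_de <- function(config) {
  paths <- sort(Sys.glob(file.path(config$study_dir, "expression_*.tsv")))
  if (length(paths) == 0L)
    stop("missing input: no expression_*.tsv in ", config$study_dir,
         " (run_simulate writes them)")
  tables <- lapply(paths, read_expression_table)
  records <- fold_changes(tables)
  filtered <- filter_de(records, config$min_fold, config$max_sd)
  top <- select_top(filtered, config$top_n)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(config$output_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(records, "fold_changes.tsv")
  wt(filtered, "de_filtered.tsv")
  wt(top$cave_under, "top_cave_under.tsv")
  wt(top$cave_over, "top_cave_over.tsv")
  invisible(list(records = records, filtered = filtered, top = top))
}

#' Run the allele-specific-expression stage
#'
#' Pairs and trims the alleles, estimates per-replicate THETA from the
#' hybrid FASTQ pairs, removes zero-THETA genes, builds and compares the
#' per-allele intra-replicate nulls, merges them, and calls ASE per gene.
#' When `genes` is supplied (e.g. the top DE genes), only those genes are
#' quantified.
#'
#' @param config a `pipeline_config`.
#' @param genes optional character vector restricting the tested genes.
#' @return list with `theta`, `null_surface`, `null_cave`, `null_merged`,
#'   `null_comparison`, `calls`, `removed`; writes `theta.tsv`,
#'   `null_distribution.tsv`, `ase_calls.tsv`, `ase_summary.json` under
#'   `output_dir`.
#' @export
run_ase <- function(config, genes = NULL) {
  fasta <- need_file(file.path(config$study_dir, "alleles.fasta"),
                     "paired-allele FASTA; run_simulate writes it")
  recs <- read_fasta(fasta)
  # population-tagged records pair within a transcript ID
  recs$annotation_id <- recs$transcript_id
  if (!is.null(genes)) recs <- recs[recs$transcript_id %in% genes, , drop = FALSE]
  surface <- recs[recs$population == "surface", , drop = FALSE]
  cave <- recs[recs$population == "cave", , drop = FALSE]
  pt <- pair_and_trim(surface, cave, config$min_identity)
  if (length(pt$pairs) == 0L) stop("no accepted allele pairs")

  r1s <- sort(Sys.glob(file.path(config$study_dir, "hybrid_rep*_R1.fastq*")))
  if (length(r1s) == 0L)
    stop("missing input: no hybrid_rep*_R1.fastq in ", config$study_dir)
  replicates <- lapply(r1s, function(p1) {
    read_fastq_pair(p1, need_file(sub("_R1", "_R2", p1), "mate-2 FASTQ"))
  })
  theta <- estimate_theta_study(
    pt$pairs, replicates,
    error_rate = config$error_rate,
    max_mismatch_rate = config$max_mismatch_rate,
    prior_pseudocount = config$prior_pseudocount,
    tol = config$tol, max_iter = config$max_iter,
    fragment_mean = config$sim$fragment_length_mean)

  zf <- filter_zero_theta(theta)
  null_s <- build_intra_allele_null(zf$estimates, "surface",
                                    ordered = config$null_ordered_pairs)
  null_c <- build_intra_allele_null(zf$estimates, "cave",
                                    ordered = config$null_ordered_pairs)
  cmp <- compare_nulls(null_s, null_c)
  merged <- merge_nulls(null_s, null_c)
  calls <- call_ase(zf$estimates, merged, config$alpha)

  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(theta, file.path(config$output_dir, "theta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  null_df <- data.frame(
    source = c(rep("surface", null_s$n), rep("cave", null_c$n)),
    log2_fc = c(null_s$values, null_c$values))
  utils::write.table(null_df,
                     file.path(config$output_dir, "null_distribution.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(calls, file.path(config$output_dir, "ase_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    n_tested = nrow(calls),
    n_significant = sum(calls$significant),
    n_not_significant = sum(!calls$significant),
    n_removed_zero_theta = nrow(zf$removed),
    null_ks_statistic = cmp$statistic,
    null_ks_p_value = cmp$p_value,
    merge_permitted = cmp$merge_permitted,
    alpha = config$alpha)
  jsonlite::write_json(summary,
                       file.path(config$output_dir, "ase_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(theta = theta, null_surface = null_s, null_cave = null_c,
                 null_merged = merged, null_comparison = cmp, calls = calls,
                 removed = zf$removed, pairing_report = pt$report))
}

#' Run the regulatory-classification stage
#'
#' Joins the DE records with the ASE calls, classifies each gene as
#' cis-concordant, trans-consistent or discordant cis-by-trans, tallies
#' concordance per DE direction, and computes the Spearman correlation of
#' DE versus ASE log2 fold changes (both oriented surface-over-cave, as in
#' the paired-bar report).
#'
#' @param config a `pipeline_config`.
#' @param de output of [run_de()] (re-read from disk when `NULL`).
#' @param ase output of [run_ase()] (re-read from disk when `NULL`).
#' @return list with `calls`, `concordance`, `correlation`; writes
#'   `regulatory_calls.tsv`, `paired_bars.tsv`, `classification_summary.json`
#'   and `report.md` under `output_dir`.
#' @export
run_classify <- function(config, de = NULL, ase = NULL) {
  if (is.null(de)) {
    p <- need_file(file.path(config$output_dir, "de_filtered.tsv"),
                   "run_de writes it")
    filtered <- utils::read.delim(p, stringsAsFactors = FALSE)
    de <- list(filtered = filtered)
  }
  if (is.null(ase)) {
    p <- need_file(file.path(config$output_dir, "ase_calls.tsv"),
                   "run_ase writes it")
    ase <- list(calls = utils::read.delim(p, stringsAsFactors = FALSE))
  }
  calls <- classify_genes(de$filtered, ase$calls)
  conc <- concordance_counts(calls)
  corr_set <- if (config$correlation_gene_set == "significant")
    calls[calls$ase_significant, , drop = FALSE] else calls
  correlation <- if (nrow(corr_set) >= 3L) {
    # both axes oriented surface-over-cave
    spearman_de_vs_ase(-corr_set$de_mean_lfc, corr_set$ase_mean_lfc)
  } else NULL

  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(calls,
                     file.path(config$output_dir, "regulatory_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  bars <- data.frame(gene_id = calls$gene_id,
                     de_surface_over_cave_lfc = -calls$de_mean_lfc,
                     de_sem = calls$de_sem_lfc,
                     ase_surface_over_cave_lfc = calls$ase_mean_lfc,
                     ase_sem = calls$ase_sem_lfc,
                     category = calls$category)
  bars <- bars[order(-bars$de_surface_over_cave_lfc), , drop = FALSE]
  utils::write.table(bars, file.path(config$output_dir, "paired_bars.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    n_classified = nrow(calls),
    categories = as.list(table(calls$category)),
    concordance = list(
      surface_favored_de = as.list(conc["cave_under", ]),
      cave_favored_de = as.list(conc["cave_over", ])),
    spearman = if (is.null(correlation)) NULL else
      list(rho = correlation$rho, p_value = correlation$p_value,
           n = correlation$n,
           gene_set = config$correlation_gene_set),
    caveats = c(
      "trans_consistent genes: cis-regulation cannot be excluded (tissue dilution)",
      "cis_concordant genes: parent-of-origin effects are indistinguishable from cis in a single cross direction"))
  jsonlite::write_json(summary,
                       file.path(config$output_dir,
                                 "classification_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_report(config, calls, conc, correlation)
  invisible(list(calls = calls, concordance = conc,
                 correlation = correlation))
}

write_report <- function(config, calls, conc, correlation) {
  out <- file.path(config$output_dir, "report.md")
  lines <- c(
    "# Hybrid ASE pipeline report", "",
    sprintf("Genes classified: %d", nrow(calls)), "",
    "## Categories", "",
    sprintf("- %s: %d", names(table(calls$category)),
            as.integer(table(calls$category))), "",
    "## Concordance among significant-ASE genes", "",
    sprintf("- surface-favored DE: %d of %d concordant",
            conc["cave_under", "n_concordant"],
            conc["cave_under", "n_total"]),
    sprintf("- cave-favored DE: %d of %d concordant",
            conc["cave_over", "n_concordant"],
            conc["cave_over", "n_total"]), "",
    if (!is.null(correlation)) {
      sprintf("Spearman DE vs ASE (%s genes): rho = %.4f, p = %.4g, n = %d",
              config$correlation_gene_set, correlation$rho,
              correlation$p_value, correlation$n)
    } else "Spearman DE vs ASE: not computed (fewer than 3 genes)", "",
    "Caveats: trans-consistent calls do not exclude cis-regulation",
    "(tissue dilution); cis-concordant calls are indistinguishable from",
    "parent-of-origin effects in a single cross direction.")
  writeLines(lines, out)
  invisible(out)
}

#' Run the full pipeline
#'
#' Simulate, DE-filter, quantify and test ASE on the top DE genes, and
#' classify. Deterministic given the config's seed.
#'
#' @param config a `pipeline_config`.
#' @return list with every stage's result, invisibly.
#' @export
run_all <- function(config) {
  manifest <- run_simulate(config)
  de <- run_de(config)
  tested <- unique(c(de$top$cave_under$gene_id, de$top$cave_over$gene_id))
  ase <- run_ase(config, genes = tested)
  de_for_classify <- list(filtered = de$filtered)
  cls <- run_classify(config, de = de_for_classify, ase = ase)
  invisible(list(manifest = manifest, de = de, ase = ase,
                 classification = cls))
}
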