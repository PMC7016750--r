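#' @useDynLib hybridase, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

BASES <- c("A", "C", "G", "T")

#' Generate a diverged surface/cave allele pair
#'
#' Draws one ancestral sequence uniformly over A/C/G/T, then substitutes each
#' site independently with probability `divergence_rate`. A substituted site
#' is mutated in exactly one allele (chosen uniformly) to a uniformly chosen
#' different base, so the recorded variant positions are exactly the sites at
#' which the two alleles differ.
#'
#' @param gene_id gene identifier.
#' @param length transcript length in bases (> 0).
#' @param divergence_rate per-site substitution probability in `[0, 1)`.
#' @param rng_seed integer seed.
#' @return a list of class `allele_pair` with fields `gene_id`,
#'   `surface_seq`, `cave_seq`, `variant_sites` (1-based positions),
#'   `identity` and `trim_intervals` (whole-sequence; this generator emits
#'   already-comparable alleles).
#' @export
generate_allele_pair <- function(gene_id, length, divergence_rate, rng_seed) {
  if (length <= 0) stop("length must be positive")
  if (divergence_rate < 0 || divergence_rate >= 1)
    stop("divergence_rate must be in [0, 1)")
  set.seed(as.integer(rng_seed))
  anc <- sample(BASES, length, replace = TRUE)
  hit <- which(stats::runif(length) < divergence_rate)
  surface <- anc
  cave <- anc
  for (pos in hit) {
    alt <- sample(setdiff(BASES, anc[pos]), 1L)
    if (stats::runif(1) < 0.5) surface[pos] <- alt else cave[pos] <- alt
  }
  new_allele_pair(
    gene_id = gene_id,
    surface_seq = paste(surface, collapse = ""),
    cave_seq = paste(cave, collapse = ""),
    variant_sites = hit,
    identity = 1 - length(hit) / length,
    trim_intervals = list(surface = c(0L, length), cave = c(0L, length))
  )
}

new_allele_pair <- function(gene_id, surface_seq, cave_seq, variant_sites,
                            identity, trim_intervals) {
  structure(
    list(gene_id = gene_id, surface_seq = surface_seq, cave_seq = cave_seq,
         variant_sites = as.integer(variant_sites), identity = identity,
         trim_intervals = trim_intervals),
    class = "allele_pair"
  )
}

seq_to_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Simulate hybrid paired-end reads from an allele pair
#'
#' Each fragment's source allele is drawn independently with probability
#' `theta_surface` (surface) versus `1 - theta_surface` (cave). Fragment
#' length is a truncated normal clamped to `[read_length, transcript
#' length]`; the fragment start is uniform over valid positions. Mates are
#' forward/reverse (R2 is the reverse complement of the fragment's 3' end),
#' and per-base miscalls are applied independently at `error_rate`.
#'
#' @param pair an `allele_pair`.
#' @param theta_surface surface-allele mixing proportion in `[0, 1]`.
#' @param n_pairs number of read pairs.
#' @param read_length read length in bases.
#' @param fragment_mean,fragment_sd fragment length distribution (bases).
#' @param error_rate per-base miscall probability.
#' @param rng_seed integer seed.
#' @return a list of class `read_pairs` with fields `r1`, `r2` (character
#'   vectors), `source` (`"surface"`/`"cave"` truth labels), `start`
#'   (1-based fragment starts) and `read_length`.
#' @export
simulate_hybrid_reads <- function(pair, theta_surface, n_pairs, read_length,
                                  fragment_mean, fragment_sd, error_rate,
                                  rng_seed) {
  stopifnot(inherits(pair, "allele_pair"))
  if (nchar(pair$surface_seq) == 0L || nchar(pair$cave_seq) == 0L)
    stop("allele sequences must be non-empty")
  if (theta_surface < 0 || theta_surface > 1)
    stop("theta_surface must be in [0, 1]")
  tlen <- nchar(pair$surface_seq)
  if (read_length > tlen)
    stop("read_length exceeds transcript length")
  set.seed(as.integer(rng_seed))
  n_pairs <- as.integer(n_pairs)
  if (n_pairs == 0L) {
    return(structure(list(r1 = character(0), r2 = character(0),
                          source = character(0), start = integer(0),
                          read_length = as.integer(read_length)),
                     class = "read_pairs"))
  }
  src <- ifelse(stats::runif(n_pairs) < theta_surface, "surface", "cave")
  flen <- round(stats::rnorm(n_pairs, fragment_mean, fragment_sd))
  flen <- pmin(pmax(flen, read_length), tlen)
  start <- floor(stats::runif(n_pairs) * (tlen - flen + 1)) + 1L
  tmpl <- ifelse(src == "surface", pair$surface_seq, pair$cave_seq)
  r1 <- substring(tmpl, start, start + read_length - 1L)
  r2_fwd <- substring(tmpl, start + flen - read_length, start + flen - 1L)
  r1 <- apply_errors(r1, error_rate, read_length)
  r2_fwd <- apply_errors(r2_fwd, error_rate, read_length)
  r2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(r2_fwd)))
  structure(list(r1 = r1, r2 = r2, source = src, start = as.integer(start),
                 read_length = as.integer(read_length)),
            class = "read_pairs")
}

# Independent per-base miscalls over a vector of equal-length read strings.
apply_errors <- function(reads, error_rate, read_length) {
  if (error_rate <= 0 || length(reads) == 0L) return(reads)
  n_err <- stats::rbinom(length(reads), read_length, error_rate)
  for (k in which(n_err > 0L)) {
    pos <- sample.int(read_length, n_err[k])
    for (p in pos) {
      orig <- substr(reads[k], p, p)
      substr(reads[k], p, p) <- sample(setdiff(BASES, orig), 1L)
    }
  }
  reads
}

#' Simulate cave/surface expression tables over several references
#'
#' For each reference transcriptome, per-gene group-mean RPKM values are set
#' by a baseline (log-normal across genes) and the gene's true cave/surface
#' fold change, perturbed by reference-level jitter; replicate values are the
#' group mean times multiplicative log-normal noise
#' (`replicate_noise_sd`, log2 scale). The same true effect drives all
#' references.
#'
#' @param config a [sim_config()].
#' @return a list with `tables` (one `expression_table` per reference) and
#'   `truth` (data frame of per-gene true theta and per-reference fold
#'   change).
#' @export
simulate_expression_tables <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$rng_seed + 77000L)
  genes <- sim_gene_ids(config)
  nrep <- config$n_replicates_per_group
  effects <- map_lookup(config$de_effect_map, genes, 1)
  thetas <- map_lookup(config$theta_map, genes, 0.5)
  baseline <- 2^stats::rnorm(length(genes), mean = 5, sd = 1.5)
  samples <- c(sprintf("cave_rep%d", seq_len(nrep)),
               sprintf("surface_rep%d", seq_len(nrep)))
  groups <- stats::setNames(rep(c("cave", "surface"), each = nrep), samples)
  tables <- vector("list", config$n_references)
  truth_fc <- matrix(NA_real_, length(genes), config$n_references,
                     dimnames = list(genes, NULL))
  for (r in seq_len(config$n_references)) {
    jit <- 2^stats::rnorm(length(genes), 0, config$reference_jitter_sd)
    fc_r <- effects * jit
    truth_fc[, r] <- fc_r
    vals <- matrix(NA_real_, length(genes), 2L * nrep,
                   dimnames = list(genes, samples))
    for (g in seq_along(genes)) {
      cave_mean <- baseline[g] * fc_r[g]
      surf_mean <- baseline[g]
      noise <- 2^stats::rnorm(2L * nrep, 0, config$replicate_noise_sd)
      vals[g, ] <- c(rep(cave_mean, nrep), rep(surf_mean, nrep)) * noise
    }
    tables[[r]] <- expression_table(sprintf("ref%d", r), vals, groups)
  }
  truth <- data.frame(
    gene_id = genes,
    theta_surface = unname(thetas),
    de_effect = unname(effects),
    stringsAsFactors = FALSE
  )
  for (r in seq_len(config$n_references))
    truth[[sprintf("fc_ref%d", r)]] <- unname(truth_fc[, r])
  list(tables = tables, truth = truth)
}

#' Generate a full synthetic study on disk
#'
#' Writes, under `output_dir`: a paired-allele FASTA (`alleles.fasta`, two
#' records per gene, headers `geneID|surface` / `geneID|cave`), per-replicate
#' hybrid FASTQ pairs (`hybrid_rep<i>_R1.fastq` / `_R2.fastq`, Sanger
#' Phred+33 with constant Q40 placeholder qualities), per-reference
#' expression tables as TSV, the ground truth as TSV, and a JSON manifest
#' listing every file with its md5 checksum.
#'
#' Per replicate, the number of read pairs per gene is Poisson around
#' `mean_depth`; sources follow each gene's `theta_map` entry.
#'
#' @param config a [sim_config()].
#' @param output_dir writable directory (created if absent).
#' @return the manifest, invisibly (list with `files` data frame and
#'   `config` echo); also written as `manifest.json`.
#' @export
generate_study <- function(config, output_dir) {
  config <- validate_sim_config(config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(output_dir)) stop("cannot create output directory: ", output_dir)
  probe <- file.path(output_dir, ".write_probe")
  ok <- tryCatch({ file.create(probe) }, warning = function(w) FALSE)
  if (!isTRUE(ok)) stop("output directory not writable: ", output_dir)
  unlink(probe)

  genes <- sim_gene_ids(config)
  thetas <- map_lookup(config$theta_map, genes, 0.5)

  # allele pairs (per-gene child seeds keep genes independent of n_genes order)
  pairs <- lapply(seq_along(genes), function(g) {
    generate_allele_pair(genes[g], config$transcript_length,
                         config$divergence_rate,
                         rng_seed = config$rng_seed + 1000L + g)
  })
  names(pairs) <- genes
  fasta_path <- file.path(output_dir, "alleles.fasta")
  write_allele_fasta(pairs, fasta_path)

  # hybrid replicates
  fastq_paths <- character(0)
  for (rep_i in seq_len(config$n_replicates_per_group)) {
    r1_all <- character(0); r2_all <- character(0); ids <- character(0)
    for (g in seq_along(genes)) {
      seed_g <- config$rng_seed + 10000L * rep_i + g
      set.seed(seed_g)
      n_pairs <- stats::rpois(1, config$mean_depth)
      rp <- simulate_hybrid_reads(pairs[[g]], thetas[g], n_pairs,
                                  config$read_length,
                                  config$fragment_length_mean,
                                  config$fragment_length_sd,
                                  config$error_rate,
                                  rng_seed = seed_g + 1L)
      if (n_pairs > 0L) {
        ids <- c(ids, sprintf("%s:rep%d:%d", genes[g], rep_i, seq_len(n_pairs)))
        r1_all <- c(r1_all, rp$r1)
        r2_all <- c(r2_all, rp$r2)
      }
    }
    p1 <- file.path(output_dir, sprintf("hybrid_rep%d_R1.fastq", rep_i))
    p2 <- file.path(output_dir, sprintf("hybrid_rep%d_R2.fastq", rep_i))
    write_fastq(ids, r1_all, p1)
    write_fastq(ids, r2_all, p2)
    fastq_paths <- c(fastq_paths, p1, p2)
  }

  # expression tables + truth
  expr <- simulate_expression_tables(config)
  table_paths <- vapply(expr$tables, function(tab) {
    p <- file.path(output_dir, sprintf("expression_%s.tsv", tab$reference_id))
    write_expression_table(tab, p)
    p
  }, character(1))
  truth <- expr$truth
  truth$n_variant_sites <- vapply(pairs, function(p) length(p$variant_sites),
                                  integer(1))[truth$gene_id]
  truth$variant_sites <- vapply(pairs, function(p) {
    paste(p$variant_sites, collapse = ",")
  }, character(1))[truth$gene_id]
  truth_path <- file.path(output_dir, "truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  files <- c(fasta_path, fastq_paths, table_paths, truth_path)
  manifest <- list(
    files = data.frame(
      path = basename(files),
      md5 = unname(tools::md5sum(files)),
      stringsAsFactors = FALSE
    ),
    n_genes = config$n_genes,
    n_hybrid_replicates = config$n_replicates_per_group,
    n_references = config$n_references,
    rng_seed = config$rng_seed,
    fastq_quality = "constant Phred 40 placeholder (qualities unused downstream)"
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

write_allele_fasta <- function(pairs, path) {
  seqs <- unlist(unname(lapply(pairs, function(p) {
    stats::setNames(c(p$surface_seq, p$cave_seq),
                    paste0(p$gene_id, c("|surface", "|cave")))
  })))
  if (is.null(seqs)) seqs <- character(0)
  xs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(xs, path)
  invisible(path)
}
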