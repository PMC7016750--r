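#' Simulation configuration for a synthetic hybrid ASE study
#'
#' Bundles every parameter of the synthetic-data generator: allele divergence,
#' hybrid read sampling, and the multi-reference cave/surface expression
#' tables. Defaults mirror a three-replicate, four-reference embryonic
#' RNA-seq design with transcripts of typical assembled length.
#'
#' @param n_genes number of genes (allele pairs) to simulate.
#' @param transcript_length transcript length in bases.
#' @param divergence_rate per-site substitution probability between the two
#'   alleles, in `[0, 1)`.
#' @param n_replicates_per_group hybrid (and per-population) replicate count.
#' @param read_length read length in bases.
#' @param mean_depth mean number of read pairs simulated per gene per
#'   replicate.
#' @param fragment_length_mean,fragment_length_sd fragment length
#'   distribution (truncated normal, clamped to
#'   `[read_length, transcript_length]`), in bases.
#' @param error_rate per-base sequencing miscall probability.
#' @param theta_map named numeric vector mapping gene id to the true
#'   surface-allele mixing proportion in `[0, 1]`; genes not named default
#'   to 0.5. `NULL` means 0.5 everywhere.
#' @param de_effect_map named numeric vector mapping gene id to the true
#'   linear cave/surface fold change; unnamed genes default to 1 (no
#'   effect). `NULL` means no differential expression.
#' @param n_references number of reference transcriptomes for the expression
#'   tables.
#' @param replicate_noise_sd standard deviation (log2 scale) of multiplicative
#'   replicate noise on RPKM values.
#' @param reference_jitter_sd standard deviation (log2 scale) of
#'   reference-level jitter on the true effect.
#' @param rng_seed integer seed; all randomness flows from it.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 100,
                       transcript_length = 1000L,
                       divergence_rate = 0.02,
                       n_replicates_per_group = 3L,
                       read_length = 100L,
                       mean_depth = 500,
                       fragment_length_mean = 250,
                       fragment_length_sd = 30,
                       error_rate = 0.005,
                       theta_map = NULL,
                       de_effect_map = NULL,
                       n_references = 4L,
                       replicate_noise_sd = 0.25,
                       reference_jitter_sd = 0.1,
                       rng_seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    transcript_length = as.integer(transcript_length),
    divergence_rate = divergence_rate,
    n_replicates_per_group = as.integer(n_replicates_per_group),
    read_length = as.integer(read_length),
    mean_depth = mean_depth,
    fragment_length_mean = fragment_length_mean,
    fragment_length_sd = fragment_length_sd,
    error_rate = error_rate,
    theta_map = theta_map,
    de_effect_map = de_effect_map,
    n_references = as.integer(n_references),
    replicate_noise_sd = replicate_noise_sd,
    reference_jitter_sd = reference_jitter_sd,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_genes < 0L) stop("n_genes must be >= 0")
  if (cfg$transcript_length <= 0L) stop("transcript_length must be positive")
  if (cfg$divergence_rate < 0 || cfg$divergence_rate >= 1)
    stop("divergence_rate must be in [0, 1)")
  if (cfg$error_rate < 0 || cfg$error_rate >= 1)
    stop("error_rate must be in [0, 1)")
  if (cfg$n_replicates_per_group < 1L)
    stop("n_replicates_per_group must be >= 1")
  if (cfg$n_references < 1L) stop("n_references must be >= 1")
  if (cfg$read_length > cfg$transcript_length)
    stop("read_length must not exceed transcript_length")
  if (cfg$fragment_length_mean < cfg$read_length ||
      cfg$fragment_length_mean > cfg$transcript_length)
    stop("fragment_length_mean must lie in [read_length, transcript_length]")
  if (!is.null(cfg$theta_map)) {
    if (any(cfg$theta_map < 0 | cfg$theta_map > 1))
      stop("theta_map proportions must be in [0, 1]")
  }
  if (!is.null(cfg$de_effect_map) && any(cfg$de_effect_map <= 0))
    stop("de_effect_map fold changes must be positive")
  cfg
}

#' Gene identifiers used by a simulation config
#' @param cfg a `sim_config`
#' @return character vector `gene001`, `gene002`, ...
#' @keywords internal
sim_gene_ids <- function(cfg) {
  if (cfg$n_genes == 0L) return(character(0))
  sprintf("gene%03d", seq_len(cfg$n_genes))
}

# Look up a per-gene map with a default for unnamed genes.
map_lookup <- function(map, gene_ids, default) {
  out <- rep(default, length(gene_ids))
  names(out) <- gene_ids
  if (!is.null(map)) {
    hit <- intersect(names(map), gene_ids)
    out[hit] <- map[hit]
  }
  out
}
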