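# Shared configuration for the numbered analysis scripts.
#
# The synthetic study mirrors the embryonic RNA-seq design the package
# models: 100 candidate genes, three hybrid replicates, four reference
# transcriptomes. Thirty genes are cis-divergent (allelic imbalance matching
# the population-level fold change), thirty are trans-divergent (fold change
# with balanced alleles), forty are null.

library(hybridase)

STUDY_SEED <- 2026L

study_config <- function(root = "results") {
  genes <- sprintf("gene%03d", 1:100)
  cis <- genes[1:30]
  trans <- genes[31:60]
  theta <- stats::setNames(rep(0.5, 100), genes)
  theta[cis[1:15]] <- 0.8
  theta[cis[16:30]] <- 0.2
  eff <- stats::setNames(rep(1, 100), genes)
  eff[cis[1:15]] <- 0.2
  eff[cis[16:30]] <- 5
  eff[trans[1:15]] <- 0.2
  eff[trans[16:30]] <- 5
  cfg <- pipeline_config(
    study_dir = file.path(root, "study"),
    output_dir = file.path(root, "pipeline"),
    sim = sim_config(n_genes = 100, transcript_length = 600,
                     divergence_rate = 0.02, read_length = 100,
                     mean_depth = 500, fragment_length_mean = 250,
                     fragment_length_sd = 30, error_rate = 0.005,
                     theta_map = theta, de_effect_map = eff,
                     rng_seed = STUDY_SEED),
    top_n = 50, rng_seed = STUDY_SEED)
  attr(cfg, "truth") <- list(cis = cis, trans = trans,
                             null = genes[61:100])
  cfg
}
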