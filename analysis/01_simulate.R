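#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study — diverged allele pairs, three
# hybrid replicates of paired-end reads at the configured allele mixing
# ratios, and cave/surface RPKM tables over four reference transcriptomes.
# Writes results/study/ and a checksummed manifest.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(FALSE), value = TRUE))), "study_config.R"))

cfg <- study_config()
manifest <- run_simulate(cfg)

cat(sprintf("Simulated %d genes x %d hybrid replicates (seed %d)\n",
            manifest$n_genes, manifest$n_hybrid_replicates,
            manifest$rng_seed))
cat(sprintf("Wrote %d files to %s (see manifest.json for checksums)\n",
            nrow(manifest$files), cfg$study_dir))
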