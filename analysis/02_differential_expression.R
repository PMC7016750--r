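#!/usr/bin/env Rscript
# Stage 2: per-reference cave/surface fold changes, the multi-reference DE
# filter (two-fold in the same direction in all four references, SD of the
# linear fold changes <= 8), and the top-50 lists per direction.

source(file.path(dirname(sub("--file=", "",
  grep("--file=", commandArgs(FALSE), value = TRUE))), "study_config.R"))

cfg <- study_config()
de <- run_de(cfg)

cat(sprintf("Fold changes computed for %d genes over %d references\n",
            nrow(de$records), length(grep("^fc_", names(de$records)))))
cat(sprintf("DE filter retained %d genes (%d under-, %d over-expressed in cave)\n",
            nrow(de$filtered),
            sum(de$filtered$direction == "cave_under"),
            sum(de$filtered$direction == "cave_over")))
cat(sprintf("Top lists: %d cave-under, %d cave-over -> %s\n",
            nrow(de$top$cave_under), nrow(de$top$cave_over),
            cfg$output_dir))
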