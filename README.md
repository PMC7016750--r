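# hybridase

Allele-specific expression (ASE) analysis of F1 hybrid RNA-seq, modelled
on cave/surface population comparisons in the isopod *Asellus aquaticus*.

A gene can differ in expression between two populations because of a
**cis**-regulatory change (at the gene) or a **trans**-regulatory change
(in a diffusible regulator). In an F1 hybrid both alleles share one trans
environment, so cis changes appear as allele-biased expression while trans
changes do not. `hybridase` implements the full analysis chain as a tested
R package:

* a **synthetic-data generator** (diverged allele pairs, hybrid paired-end
  reads at known mixing ratios θ, multi-reference cave/surface RPKM
  tables) so every stage is testable against known truth;
* **RPKM** normalisation, multi-hit averaging, and the multi-reference DE
  filter (fold change ≥ 2 in the same direction in all four references,
  SD of the linear fold changes ≤ 8; top 50 genes per direction);
* automated **allele pairing and trimming** by local alignment
  (match +1, mismatch −1, gap open −2, gap extend −0.5; identity ≥ 0.9);
* **EM estimation of per-allele abundance (THETA)** from hybrid reads:
  read likelihood (e/3)^m (1−e)^(L−m) per allele at the best ungapped
  offset, Dirichlet pseudocount, effective-length normalisation;
* a **replicate-derived intra-allele null**: pooled
  log2(θ_i/θ_j) over ordered replicate pairs within each allele, checked
  for surface/cave indistinguishability and merged;
* **ASE calls**: per gene, the nine inter-allele values
  log2(θ^surf_i/θ^cave_j) are tested against the merged null with a
  two-sample Kolmogorov–Smirnov test (exact permutation p for small
  samples, asymptotic otherwise) and Benjamini–Hochberg FDR at α = 0.05;
* **regulatory classification**: `cis_concordant` (significant ASE,
  direction agreeing with DE), `trans_consistent` (no significant ASE),
  `discordant_cis_by_trans` (significant ASE opposing DE), with
  concordance tallies and a Spearman DE-vs-ASE correlation.

See `vignettes/hybrid-ase-workflow.Rmd` for the models, parameter
defaults, and known limitations (in particular why the K–S caller is
liberal on balanced genes).

## Worked example

The `analysis/` directory is a numbered workflow over a packaged synthetic
study (100 genes: 30 cis-divergent, 30 trans-divergent, 40 null; three
hybrid replicates; four references; seed 2026):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_differential_expression.R
Rscript analysis/03_allele_specific_expression.R
Rscript analysis/04_regulatory_classification.R
```

which prints, stage by stage:

```
Simulated 100 genes x 3 hybrid replicates (seed 2026)
DE filter retained 60 genes (30 under-, 30 over-expressed in cave)
Tested 60 genes (0 removed by the zero-THETA filter)
Surface vs cave null: K-S statistic 0.0333, p = 0.9883 (indistinguishable; merged)
Merged null: 720 intra-allele log2 fold changes
Significant ASE at alpha 0.05: 49 of 60 genes
         cis_concordant discordant_cis_by_trans        trans_consistent
                     41                       8                      11
Concordance among significant-ASE genes: 19/23 (surface-favored DE), 22/26 (cave-favored DE)
Spearman DE vs ASE (significant genes): rho = 0.6354, p = 9.35e-07, n = 49
Truth recovery: 100% of cis genes cis-concordant, 37% of trans genes trans-consistent
```

Reading those numbers: the DE filter recovers exactly the 60 genes with a
true five-fold effect; the surface and cave intra-allele nulls are
statistically indistinguishable (K–S p ≈ 0.99), licensing the merge; all
30 cis-divergent genes are recovered as cis-concordant with DE and ASE
fold changes strongly rank-correlated. The low trans recovery is a real
property of the replicate-pairing design — balanced genes share
replicate-level estimation noise across all nine inter-allele values, so
the K–S caller flags many of them — and is analysed in the vignette.
Tables behind each stage land in `results/` (`fold_changes.tsv`,
`theta.tsv`, `null_distribution.tsv`, `ase_calls.tsv`,
`regulatory_calls.tsv`, `paired_bars.tsv`, JSON summaries, `report.md`).

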