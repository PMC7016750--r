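---
title: "Detecting cis-regulatory divergence from hybrid allele-specific expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cis-regulatory divergence from hybrid allele-specific expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridase)
```

## The question the pipeline answers

Cave-dwelling populations of the isopod *Asellus aquaticus* differ from
their surface relatives in eye and pigment development, and many of those
differences are transcriptional. A gene can be differentially expressed
(DE) between the two populations for two very different reasons:

* a **cis-regulatory** change — a sequence change at the gene itself that
  alters its expression; or
* a **trans-regulatory** change — a change in a diffusible regulator that
  acts on the gene from elsewhere.

F1 hybrids separate the two. Both parental alleles of a hybrid share one
nucleus and therefore one trans environment, so a cis change shows up as
**allele-specific expression (ASE)**: reads from the hybrid preferentially
carry the variant bases of one allele. A trans change affects both alleles
equally and produces no ASE. A gene that is DE between populations and has
significant ASE in hybrids *in the same direction* is consistent with cis
regulation; DE without ASE is consistent with trans regulation (with the
caveat below); significant ASE *opposing* the DE direction suggests
compensating cis-by-trans effects.

`hybridase` implements that whole chain as testable, seeded code: a
synthetic-data generator stands in for the study's raw sequencing data, so
every stage can be exercised against known truth.

## Stages and their models

### 1. Expression tables and the multi-reference DE filter

Counts are normalised as RPKM,
$\mathrm{RPKM}_{gs} = c_{gs} \big/ \left(\tfrac{L_g}{10^3}\cdot
\tfrac{N_s}{10^6}\right)$, with $N_s$ the column total. Contigs hitting the
same reference gene are collapsed by the arithmetic mean of their RPKM.
Reads are mapped (upstream of this package) against four reference
transcriptomes — cave, surface, hybrid, integrated — and per reference the
linear fold change is the ratio of cave to surface group means. A gene is
retained when

* the fold change is at least two-fold **in the same direction in every
  reference**, and
* the sample standard deviation of the four per-reference *linear* fold
  changes is at most 8.

The "standard deviation of 8" rule is only plausible on the linear
fold-change scale (log2 fold changes of embryonic genes rarely have an SD
near 8), so that is the scale `sd_statistic` uses; the quantity is exposed
and configurable. Group means are plain arithmetic means of replicate
RPKM. A pseudocount (0.1 RPKM, added to both group means) is applied
**only when a group mean is exactly zero**: an unconditional pseudocount
would silently bias every reported ratio, whereas the conditional one
leaves ordinary genes untouched and keeps degenerate genes finite and
flagged (`pseudocount_adjusted`). The top 50 genes per direction, ranked
by |mean log2 fold change| with lexicographic tie-breaks, proceed to ASE.

### 2. Allele pairing and trimming

Cave/surface transcript pairs are matched by a shared annotation ID. The
study this models trimmed pairs to comparable regions by hand; a reusable
pipeline needs that automated, so `trim_pair()` computes a local alignment
(match +1, mismatch −1, gap open −2, gap extend −0.5 — mild gap costs suit
assembled transcripts whose ends, not cores, disagree) and keeps the
maximal-scoring block. Identity is matching columns over all alignment
columns; pairs under `min_identity = 0.90` are recorded as rejected rather
than silently dropped — below roughly 90% identity two "alleles" are more
likely paralogues or mis-annotations than alleles of one gene. `N` bases
mismatch everything, including other `N`s, so runs of ambiguity can never
inflate identity. Variant sites are the non-gap mismatch columns in
trimmed-surface coordinates; trim intervals are 0-based half-open. When an
annotation ID is ambiguous (several transcripts in one population), every
combination is aligned and the highest-identity pairing wins, because ASE
needs exactly one pair per gene.

### 3. Allele abundance (THETA) by EM

Each hybrid read pair is placed on each trimmed allele at its best
ungapped offset, both strands, and scored
$P(\text{read}\mid a) = (e/3)^{m}(1-e)^{L-m}$ with $m$ mismatches over
aligned length $L$ and $e$ the assumed per-base error rate; mates
multiply. Ungapped placement is exact for substitution-diverged alleles
(the generator's model) and fast enough for desk-scale studies; indels in
real pairs are absorbed by the trimming stage. Pairs whose better allele
still exceeds a 10% mismatch rate fail the score gate and are counted,
not errored. The C++ scorer counts mismatches exactly up to that gate and
clamps beyond it, which provably never changes a gate decision or a
retained read's likelihood.

The allele of origin is latent, so abundance is estimated by EM: the
E-step assigns each pair fractionally in proportion to
$\theta_a \cdot P(\text{read}\mid a)$, and the M-step sets
$\theta_a \propto (\text{fractional count}_a + \text{prior}) /
\tilde L_a$ with effective length $\tilde L_a = \max(1, L_a -
\bar\ell_\mathrm{frag} + 1)$. The Dirichlet pseudocount (default 1.0, a
posterior-mean reading of the Bayesian estimator this stage reimplements)
keeps estimates off the boundary at low depth. Reads matching both
alleles equally stay in at 50/50 — discarding them would overweight
divergent regions. Iteration stops when $\max|\Delta\theta| < 10^{-6}$ or
at 500 iterations (returned with a convergence flag; the data likelihood
is non-decreasing by construction and asserted in tests). Per gene and
replicate the two thetas sum to one; `expected_fragments` sum to the
retained read count, and FPKM uses the replicate's total retained pairs
as library size.

### 4. The intra-allele null and ASE calls

Genes with any zero or undefined theta in any replicate of either allele
are removed. For each remaining gene the **intra-allele null** collects
$\log_2(\theta_i/\theta_j)$ over ordered replicate pairs $i \ne j$ within
an allele: with both orderings included the pooled null is symmetric about
zero by construction, which avoids an arbitrary replicate order (the
unordered variant is available via `ordered = FALSE`). The surface and
cave nulls are compared by a two-sample Kolmogorov–Smirnov test; merging
proceeds regardless, but the `merge_permitted` flag reports whether they
were statistically indistinguishable, mirroring how the procedure is meant
to be used.

Per gene, the nine inter-allele values
$\log_2(\theta^{\mathrm{surf}}_i / \theta^{\mathrm{cave}}_j)$ (all $3
\times 3$ replicate combinations) are tested against the merged null with
the same K–S test, and p-values are Benjamini–Hochberg adjusted at
$\alpha = 0.05$. Direction is the sign of the mean inter-allele log2 fold
change. The K–S statistic is the supremum of the ECDF difference
evaluated at the pooled points (ties handled by construction); the
p-value is the exact permutation probability — computed by lattice-path
counting conditional on the observed tie pattern — whenever the smaller
sample has at most 25 values, and the asymptotic Kolmogorov distribution
with effective size $nm/(n+m)$ otherwise. The exact routine is verified
in the test suite against exhaustive enumeration of all
$\binom{n+m}{n}$ assignments for $n, m \le 8$ and against
`stats::ks.test` at larger sizes; B–H is verified against a literal
step-up reference and `stats::p.adjust`. Parametric fits to the null are
deliberately not used for inference — the nonparametric test is the point.

### 5. Regulatory classification

With DE direction, ASE significance and ASE direction in hand, each gene
is classified:

| ASE significant | directions agree | category |
|---|---|---|
| yes | yes | `cis_concordant` |
| no | — | `trans_consistent` |
| yes | no | `discordant_cis_by_trans` |

`trans_consistent` is deliberately not called "trans": a cis effect can
hide when the relevant tissue is diluted in whole-embryo RNA, so absence
of ASE does not exclude cis regulation. Likewise parent-of-origin
(imprinting-like) effects are indistinguishable from cis effects in a
single cross direction; the report repeats both caveats. The DE-versus-ASE
association is summarised by a Spearman correlation (average ranks for
ties, two-sided t approximation on $n-2$ degrees of freedom), computed by
default over the significant-ASE genes with both axes oriented
surface-over-cave; the tested gene set is explicit and switchable because
either convention is defensible.

## The synthetic generator: what it emulates, and what it does not

The generator reproduces the statistical structure the analysis assumes:

* **Allele pairs** descend from one ancestral sequence; each site is
  substituted with probability `divergence_rate` (default 0.02, matching
  a few-percent cave/surface divergence) in exactly one allele, to a
  uniformly chosen different base. This is the simplest model that makes
  diagnostic-site inference well-posed; recorded variant positions are by
  construction exactly the differing sites.
* **Hybrid reads**: each fragment picks the surface allele with
  probability `theta_map[gene]`, a truncated-normal fragment length
  clamped to `[read_length, transcript_length]` (standard RNA-seq
  convention), uniform start, forward/reverse mates, and independent
  per-base miscalls. FASTQ qualities are a constant Phred-40 placeholder,
  recorded as such in the manifest, because qualities are not used
  downstream.
* **Expression tables**: per reference, group means follow a log-normal
  baseline times the gene's true fold change with reference-level jitter
  (log2 SD 0.1), and replicates add multiplicative log-normal noise
  (log2 SD 0.25) — the multiplicative scale matches the log-fold-change
  analyses downstream. Replicate noise magnitude is a free parameter: the
  study this models gives no estimate of brood-to-brood expression
  variance.

It does **not** simulate assembly artifacts, chimeric contigs, isoforms
or paralogues (the upstream study could not evaluate those either), nor
base-quality structure, GC or positional bias, or correlated ASE
estimation errors. Passing tests therefore demonstrate correctness of the
statistical machinery under the stated model, not robustness to
assembly- or library-level pathologies of real data.

All randomness flows from `rng_seed`; per-gene and per-replicate child
seeds make studies bit-reproducible (checksummed manifests are compared
in the tests).

## Known limitation: the caller is liberal on balanced genes

Because the two thetas of a gene sum to one within each replicate, the
replicate-level estimation error enters the intra-allele null as a
*difference* ($\delta_i - \delta_j$ on the log scale) but every
inter-allele value as a *sum* ($\delta_i + \delta_j$). All nine values of
a gene therefore share the coherent shift $2\bar\delta$, whose standard
deviation ($2\sigma/\sqrt{3}$ with three replicates) is comparable to the
null's width ($\sqrt{2}\sigma$). The K–S test detects that coherent shift,
so genes with perfectly balanced alleles are flagged far more often than
the nominal $\alpha$: the acceptance suite measures a null significant
fraction around 0.4 at $\alpha = 0.05$, invariant to sequencing depth
(both the shift and the null width scale with the same $\sigma$). The
same machinery is verified to be calibrated when a gene's nine values are
genuinely exchangeable with the null, so this is a property of the
replicate-pairing design, not of the implementation. Consequences:

* "significant ASE" from this procedure is evidence of
  *replicate-coherent* allelic imbalance, and the effective false
  discovery rate among balanced genes is well above $\alpha$;
* `trans_consistent` recovery on truly trans-regulated genes plateaus
  around 40–60% in the end-to-end synthetic study, while strongly
  imbalanced genes (|log2 ratio| around 2) are recovered essentially
  always, with the correct direction;
* a conceivable remedy — a null built from *sums* of independent
  replicate deviations, or gene-level mixed models — would depart from
  the procedure this package sets out to implement, so it is noted here
  rather than silently substituted.

A related degenerate case: a gene whose replicates agree *exactly*
(all nine values identical) concentrates its ECDF in a single step, which
a K–S test against a wide null flags as significant on dispersion alone.
Such genes are visible in the output by their zero `sem_lfc`.

The pooled null also absorbs gene-level variance heterogeneity: genes
noisier than average are tested against a too-narrow null and vice versa.
This follows the pooled-null design and is stated in the report output.

## Problem sizes and numerical choices

The packaged study and the acceptance suite run at desk scale, chosen so
the full suite completes comfortably on one CPU: transcripts of 600–1000
bases, 100-base reads, per-gene depths of 150–2000 pairs, 100-gene
studies, three replicates, four references. EM tolerance is $10^{-6}$ on
theta with a 500-iteration cap; exact K–S p-values switch to the
asymptotic form above a smaller-sample size of 25; the read score gate is
a 10% mismatch rate; alignment scoring and all thresholds above are
config-exposed (`pipeline_config()`), with defaults equal to the study
values where the study states one (two-fold, SD 8, top 50, $\alpha =
0.05$, three replicates, four references).
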