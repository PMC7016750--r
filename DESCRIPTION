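Package: hybridase
Title: Allele-Specific Expression Analysis of F1 Hybrid Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for detecting allele-specific expression
    (ASE) and cis/trans regulatory divergence from F1 hybrid RNA-seq data,
    modelled on studies of cave versus surface populations of the isopod
    Asellus aquaticus. Provides a synthetic-data generator (diverged allele
    pairs, hybrid paired-end reads at known mixing ratios, multi-reference
    expression tables), automated allele pairing and trimming by local
    alignment, EM estimation of per-allele transcript abundance (THETA) from
    hybrid reads, RPKM-based multi-reference differential-expression
    filtering, a replicate-derived intra-allele null distribution,
    two-sample Kolmogorov-Smirnov testing with Benjamini-Hochberg FDR
    control, and classification of genes into cis-concordant,
    trans-consistent and discordant cis-by-trans regulatory categories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
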