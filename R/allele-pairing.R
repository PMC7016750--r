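#' Candidate allele pairs by shared annotation ID
#'
#' One candidate per annotation ID present in both populations. When an ID
#' maps to several transcripts in one population, every combination is
#' aligned and the highest-identity pairing is kept; the conflict is
#' recorded in the `conflicts` attribute.
#'
#' @param surface,cave transcript record data frames ([read_fasta()]) with
#'   `annotation_id` set.
#' @return data frame with columns `gene_id` (the shared annotation ID),
#'   `surface_transcript_id`, `cave_transcript_id`, `surface_seq`,
#'   `cave_seq`; attribute `conflicts` is a character vector of multi-mapping
#'   IDs that were resolved by best identity.
#' @export
pair_by_annotation <- function(surface, cave) {
  s <- surface[!is.na(surface$annotation_id), , drop = FALSE]
  c_ <- cave[!is.na(cave$annotation_id), , drop = FALSE]
  shared <- intersect(s$annotation_id, c_$annotation_id)
  if (length(shared) == 0L) {
    warning("no shared annotation IDs between populations")
  }
  conflicts <- character(0)
  rows <- lapply(shared, function(id) {
    si <- s[s$annotation_id == id, , drop = FALSE]
    ci <- c_[c_$annotation_id == id, , drop = FALSE]
    if (nrow(si) > 1L || nrow(ci) > 1L) {
      conflicts <<- c(conflicts, id)
      combos <- expand.grid(i = seq_len(nrow(si)), j = seq_len(nrow(ci)))
      ident <- mapply(function(i, j) {
        alignment_identity(si$sequence[i], ci$sequence[j])
      }, combos$i, combos$j)
      best <- which.max(ident)
      si <- si[combos$i[best], , drop = FALSE]
      ci <- ci[combos$j[best], , drop = FALSE]
    }
    data.frame(gene_id = id,
               surface_transcript_id = si$transcript_id,
               cave_transcript_id = ci$transcript_id,
               surface_seq = si$sequence, cave_seq = ci$sequence,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), surface_transcript_id = character(0),
               cave_transcript_id = character(0), surface_seq = character(0),
               cave_seq = character(0), stringsAsFactors = FALSE)
  attr(out, "conflicts") <- conflicts
  out
}

# Substitution matrix: +1 match, -1 mismatch; N mismatches every base,
# including N itself (assembled transcripts may carry Ns).
ase_substitution_matrix <- function() {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(-1, 5, 5, dimnames = list(b, b))
  diag(m)[1:4] <- 1
  m["N", "N"] <- -1
  m
}

align_local <- function(surface_seq, cave_seq) {
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(surface_seq),
    subject = Biostrings::DNAString(cave_seq),
    type = "local",
    substitutionMatrix = ase_substitution_matrix(),
    gapOpening = 2, gapExtension = 0.5)
}

alignment_identity <- function(surface_seq, cave_seq) {
  aln <- align_local(surface_seq, cave_seq)
  p <- seq_to_chars(as.character(Biostrings::alignedPattern(aln)))
  s <- seq_to_chars(as.character(Biostrings::alignedSubject(aln)))
  if (length(p) == 0L) return(0)
  sum(p == s & p != "-" & p != "N") / length(p)
}

#' Trim an allele pair to its comparable high-identity region
#'
#' Runs a pairwise local alignment (match +1, mismatch -1, gap open -2, gap
#' extend -0.5; N mismatches everything) and keeps the maximal-scoring
#' aligned block of each sequence. Identity is the proportion of matching
#' columns over all alignment columns; pairs below `min_identity` are
#' returned with `accepted = FALSE` (a rejection record, not an error).
#' Variant sites are the non-gap mismatch columns, in coordinates of the
#' trimmed surface sequence; gap columns are excluded. Trim intervals are
#' 0-based half-open on each original sequence.
#'
#' @param surface_seq,cave_seq untrimmed allele sequences.
#' @param gene_id gene identifier carried onto the result.
#' @param min_identity minimum alignment identity to accept a pair.
#' @return an `allele_pair` with fields `gene_id`, `surface_seq`, `cave_seq`
#'   (trimmed), `trim_intervals`, `identity`, `variant_sites`, `accepted`.
#' @export
trim_pair <- function(surface_seq, cave_seq, min_identity = 0.90,
                      gene_id = NA_character_) {
  if (nchar(surface_seq) == 0L || nchar(cave_seq) == 0L)
    stop("allele sequences must be non-empty")
  aln <- align_local(surface_seq, cave_seq)
  p <- seq_to_chars(as.character(Biostrings::alignedPattern(aln)))
  s <- seq_to_chars(as.character(Biostrings::alignedSubject(aln)))
  ncol_aln <- length(p)
  identity <- if (ncol_aln) sum(p == s & p != "-" & p != "N") / ncol_aln else 0
  ps <- Biostrings::start(Biostrings::pattern(aln))
  pe <- Biostrings::end(Biostrings::pattern(aln))
  ss <- Biostrings::start(Biostrings::subject(aln))
  se <- Biostrings::end(Biostrings::subject(aln))
  nongap <- p != "-" & s != "-"
  mism <- nongap & (p != s | p == "N" | s == "N")
  # trimmed-surface coordinate of each alignment column = count of non-gap
  # pattern characters up to it
  surf_pos <- cumsum(p != "-")
  pair <- new_allele_pair(
    gene_id = gene_id,
    surface_seq = substr(surface_seq, ps, pe),
    cave_seq = substr(cave_seq, ss, se),
    variant_sites = surf_pos[mism],
    identity = identity,
    trim_intervals = list(surface = c(ps - 1L, pe), cave = c(ss - 1L, se))
  )
  pair$accepted <- identity >= min_identity
  pair
}

#' Pair and trim two annotated transcriptomes
#'
#' Convenience wrapper: [pair_by_annotation()] followed by [trim_pair()] on
#' every candidate, with a per-gene pairing report.
#'
#' @inheritParams pair_by_annotation
#' @param min_identity passed to [trim_pair()].
#' @return list with `pairs` (named list of accepted `allele_pair`s) and
#'   `report` (data frame: gene_id, identity, trim intervals, number of
#'   variant sites, accepted flag).
#' @export
pair_and_trim <- function(surface, cave, min_identity = 0.90) {
  cand <- pair_by_annotation(surface, cave)
  pairs <- lapply(seq_len(nrow(cand)), function(i) {
    trim_pair(cand$surface_seq[i], cand$cave_seq[i], min_identity,
              gene_id = cand$gene_id[i])
  })
  report <- data.frame(
    gene_id = cand$gene_id,
    identity = vapply(pairs, `[[`, numeric(1), "identity"),
    surface_trim_start = vapply(pairs, function(p) p$trim_intervals$surface[1], numeric(1)),
    surface_trim_end = vapply(pairs, function(p) p$trim_intervals$surface[2], numeric(1)),
    cave_trim_start = vapply(pairs, function(p) p$trim_intervals$cave[1], numeric(1)),
    cave_trim_end = vapply(pairs, function(p) p$trim_intervals$cave[2], numeric(1)),
    n_variant_sites = vapply(pairs, function(p) length(p$variant_sites), integer(1)),
    accepted = vapply(pairs, `[[`, logical(1), "accepted"),
    stringsAsFactors = FALSE
  )
  keep <- pairs[report$accepted]
  names(keep) <- report$gene_id[report$accepted]
  list(pairs = keep, report = report)
}
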