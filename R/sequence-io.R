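#' Read transcript records from FASTA
#'
#' Headers are parsed as `id[|population]` with an optional `annot=<ID>` key
#' in the description (the cross-population pairing key, e.g. a shared
#' Uniprot ID). Order is preserved.
#'
#' @param path FASTA file (plain or gzip).
#' @return data frame with columns `transcript_id`, `population`
#'   (`surface`/`cave`/`hybrid`/`integrated` or `NA`), `annotation_id`
#'   (`NA` if absent) and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  # BStringSet preserves invalid letters so validation can name the record
  xs <- Biostrings::readBStringSet(path)
  headers <- names(xs)
  seqs <- as.character(xs)
  id_part <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  annot <- ifelse(grepl("annot=", desc),
                  sub("^.*annot=(\\S+).*$", "\\1", desc), NA_character_)
  has_pop <- grepl("\\|", id_part)
  transcript_id <- ifelse(has_pop, sub("\\|.*$", "", id_part), id_part)
  population <- ifelse(has_pop, sub("^[^|]*\\|", "", id_part), NA_character_)
  key <- ifelse(is.na(population), transcript_id,
                paste(transcript_id, population, sep = "|"))
  if (anyDuplicated(key))
    stop("duplicate transcript IDs in ", path, ": ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-nucleotide symbols in record(s): ",
         paste(key[bad], collapse = ", "))
  data.frame(transcript_id = transcript_id, population = population,
             annotation_id = annot, sequence = seqs,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write transcript records to FASTA
#'
#' Inverse of [read_fasta()]: headers are `id[|population][ annot=<ID>]`.
#'
#' @param records data frame as returned by [read_fasta()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  headers <- records$transcript_id
  if (!is.null(records$population)) {
    has <- !is.na(records$population)
    headers[has] <- paste(headers[has], records$population[has], sep = "|")
  }
  if (!is.null(records$annotation_id)) {
    has <- !is.na(records$annotation_id)
    headers[has] <- paste0(headers[has], " annot=", records$annotation_id[has])
  }
  xs <- Biostrings::DNAStringSet(stats::setNames(records$sequence, headers))
  Biostrings::writeXStringSet(xs, path)
  invisible(path)
}

#' Read a paired-end FASTQ file pair
#'
#' Mates are matched by order; the two files must contain the same number of
#' records. Gzip-compressed inputs are accepted transparently.
#'
#' @param path_r1,path_r2 FASTQ files for mate 1 and mate 2.
#' @return a `read_pairs` object (fields `r1`, `r2`, `id`, `read_length`).
#' @export
read_fastq_pair <- function(path_r1, path_r2) {
  for (p in c(path_r1, path_r2))
    if (!file.exists(p)) stop("file not found: ", p)
  x1 <- Biostrings::readDNAStringSet(path_r1, format = "fastq")
  x2 <- Biostrings::readDNAStringSet(path_r2, format = "fastq")
  if (length(x1) != length(x2))
    stop("R1/R2 record counts differ (", length(x1), " vs ", length(x2), ")")
  structure(list(r1 = as.character(unname(x1)), r2 = as.character(unname(x2)),
                 id = names(x1),
                 read_length = if (length(x1)) Biostrings::width(x1)[1] else NA_integer_),
            class = "read_pairs")
}

#' Write one FASTQ file (constant Q40 placeholder qualities)
#' @param ids read identifiers.
#' @param seqs read sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(ids, seqs, path) {
  stopifnot(length(ids) == length(seqs))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(seqs)) {
    qual <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), con)
  }
  invisible(path)
}

#' Expression table container
#'
#' @param reference_id which reference transcriptome the reads were mapped to.
#' @param values numeric matrix of RPKM, genes x samples (dimnames required).
#' @param groups named character vector mapping sample id to group
#'   (`cave`/`surface`).
#' @return an object of class `expression_table`.
#' @export
expression_table <- function(reference_id, values, groups) {
  stopifnot(is.matrix(values), !is.null(colnames(values)))
  if (nrow(values) > 0 && is.null(rownames(values)))
    stop("values must carry gene rownames")
  if (any(values < 0)) stop("expression values must be >= 0")
  groups <- groups[colnames(values)]
  if (anyNA(groups)) stop("every sample needs a group label")
  structure(list(reference_id = reference_id, values = values,
                 groups = groups),
            class = "expression_table")
}

#' Read an expression table from TSV
#'
#' Expects a header row of sample IDs, a first column of gene IDs, and fully
#' numeric cells. Group labels are taken from a `cave`/`surface` prefix of
#' each sample ID unless supplied.
#'
#' @param path TSV file.
#' @param reference_id reference label (defaults to the file name stem).
#' @param groups optional named group vector; inferred from sample-ID
#'   prefixes when `NULL`.
#' @return an `expression_table`.
#' @export
read_expression_table <- function(path, reference_id = NULL, groups = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(reference_id))
    reference_id <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("expression table needs gene-ID and sample columns")
  genes <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) | vals == "", arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric or missing cell at gene '%s', sample '%s'",
                 genes[bad[1, 1]], colnames(vals)[bad[1, 2]]))
  dimnames(num) <- list(genes, colnames(vals))
  if (is.null(groups)) {
    groups <- stats::setNames(sub("_.*$", "", colnames(num)), colnames(num))
  }
  expression_table(reference_id, num, groups)
}

#' Write an expression table to TSV
#' @param table an `expression_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(table, path) {
  df <- data.frame(gene_id = rownames(table$values), table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
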