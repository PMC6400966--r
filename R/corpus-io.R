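#' Read a corpus from FASTA plus a metadata table
#'
#' Loads sequences from a (multi-record) FASTA file and joins them with a
#' tab-separated metadata table carrying, per record id, the nucleic-acid
#' type and optionally the host lineage. The FASTA header up to the first
#' whitespace is the record id.
#'
#' @param fasta_path Path to a FASTA file (DNA or RNA alphabet).
#' @param metadata_path Path to a TSV with columns `id`, `nucleic_acid` and
#'   optionally `host_lineage`. If `NULL`, every record defaults to DNA with
#'   no lineage (useful for prediction-only input).
#' @return Data frame with columns `id`, `residues`, `nucleic_acid`,
#'   `host_lineage`.
#' @export
read_corpus <- function(fasta_path, metadata_path = NULL) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  corpus <- data.frame(
    id = ids,
    residues = as.character(seqs),
    nucleic_acid = "DNA",
    host_lineage = NA_character_,
    stringsAsFactors = FALSE
  )
  if (!is.null(metadata_path)) {
    meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
    if (!all(c("id", "nucleic_acid") %in% names(meta))) {
      stopf("metadata table must have columns id and nucleic_acid")
    }
    m <- match(corpus$id, meta$id)
    if (anyNA(m)) {
      stopf("metadata missing for record(s): %s",
            paste(corpus$id[is.na(m)], collapse = ", "))
    }
    corpus$nucleic_acid <- toupper(meta$nucleic_acid[m])
    if ("host_lineage" %in% names(meta)) {
      corpus$host_lineage <- meta$host_lineage[m]
    }
  }
  corpus
}

#' Write a corpus to FASTA plus a metadata table
#'
#' Inverse of [read_corpus()]: writes the sequences as FASTA and the record
#' metadata (`id`, `nucleic_acid`, `host_lineage`, plus any extra columns
#' such as `class`) as a TSV.
#'
#' @param corpus Corpus data frame (see [read_corpus()]).
#' @param fasta_path,metadata_path Output paths.
#' @return Invisibly, the corpus.
#' @export
write_corpus <- function(corpus, fasta_path, metadata_path) {
  seqs <- Biostrings::BStringSet(setNames(corpus$residues, corpus$id))
  Biostrings::writeXStringSet(seqs, fasta_path)
  meta <- corpus[, setdiff(names(corpus), "residues"), drop = FALSE]
  utils::write.table(meta, metadata_path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(corpus)
}

#' Write a feature matrix as TSV
#'
#' @param X Feature matrix from [extract_feature_matrix()].
#' @param path Output path; the header row carries the schema names and the
#'   first column the record ids.
#' @return Invisibly, `path`.
#' @export
write_feature_matrix <- function(X, path) {
  df <- data.frame(id = rownames(X), X, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
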