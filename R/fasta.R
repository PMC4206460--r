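# FASTA input/output for protein databases.

#' Read a protein FASTA database
#'
#' Reads a (multi-line) amino-acid FASTA file. The accession of each entry is
#' the first whitespace-delimited token of the header; UniProt-style headers
#' (`sp|ACC|NAME` or `tr|ACC|NAME`) are parsed down to `ACC`.
#'
#' @param path Path to a FASTA file.
#' @return A `data.frame` with columns `accession` and `sequence` (uppercase).
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("FASTA file contains no sequences: ", path)
  acc <- vapply(strsplit(names(aa), "[ \t]"), `[`, character(1), 1L)
  up <- grepl("^(sp|tr)\\|", acc)
  acc[up] <- vapply(strsplit(acc[up], "|", fixed = TRUE), `[`, character(1), 2L)
  seqs <- toupper(as.character(aa))
  if (any(!nzchar(seqs))) stop("FASTA contains empty sequences")
  if (anyDuplicated(acc)) {
    stop("duplicated accessions in FASTA: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  }
  data.frame(accession = acc, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write a protein database to FASTA
#'
#' @param database A `data.frame` with columns `accession` and `sequence`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(database, path) {
  check_database(database)
  aa <- Biostrings::AAStringSet(database$sequence)
  names(aa) <- database$accession
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

# Validate the in-memory protein database representation.
check_database <- function(database) {
  if (!is.data.frame(database) ||
      !all(c("accession", "sequence") %in% names(database))) {
    stop("database must be a data.frame with columns 'accession' and 'sequence'")
  }
  if (nrow(database) == 0L) stop("database is empty")
  if (any(!nzchar(database$sequence))) stop("database contains empty sequences")
  if (anyDuplicated(database$accession)) stop("database accessions must be unique")
  invisible(database)
}
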