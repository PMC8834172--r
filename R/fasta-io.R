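#' Read and write FASTA files
#'
#' Thin wrappers around Biostrings that return the package's sequence
#' records. `read_protein_fasta()` / `read_coding_fasta()` read every record
#' in the file; writers emit standard wrapped FASTA.
#'
#' @param path file path.
#' @param records a single record or a list of records.
#' @return Readers return a named list of [protein_record()] /
#'   [coding_record()] objects (names are the FASTA ids).
#' @export
read_protein_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  recs <- lapply(seq_along(ss), function(i) {
    protein_record(fasta_id(names(ss)[i]), as.character(ss[[i]]))
  })
  stats::setNames(recs, vapply(recs, `[[`, "", "id"))
}

#' @rdname read_protein_fasta
#' @export
read_coding_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  recs <- lapply(seq_along(ss), function(i) {
    coding_record(fasta_id(names(ss)[i]), as.character(ss[[i]]))
  })
  stats::setNames(recs, vapply(recs, `[[`, "", "id"))
}

#' @rdname read_protein_fasta
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, c("protein_record", "coding_record"))) {
    records <- list(records)
  }
  seqs <- vapply(records, function(r) {
    if (!is.null(r$residues)) r$residues else r$nucleotides
  }, "")
  ids <- vapply(records, `[[`, "", "id")
  ss <- Biostrings::BStringSet(stats::setNames(seqs, ids))
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

# first whitespace-delimited token of a FASTA header
fasta_id <- function(header) sub("\\s.*$", "", header)
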