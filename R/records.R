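#' Sequence records
#'
#' `protein_record()` holds an identified amino-acid sequence over the 20
#' canonical residues plus `X` (unknown). `coding_record()` holds a
#' nucleotide sequence over `ACGT` plus `N`, with a declared reading-frame
#' offset. Input sequences may not contain gap characters; gaps only appear
#' in alignment rows.
#'
#' @param id character scalar identifier.
#' @param residues amino-acid sequence (single string, upper case).
#' @param nucleotides nucleotide sequence (single string, upper case).
#' @param frame_offset 0, 1 or 2 bases skipped before the first codon.
#' @return An object of class `protein_record` or `coding_record` with
#'   elements `id` and `residues`/`nucleotides`.
#' @examples
#' protein_record("toy", "MKVLA")
#' coding_record("toy", "ATGGCC")
#' @export
protein_record <- function(id, residues) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (nchar(residues) == 0L) stop("protein sequence '", id, "' is empty")
  check_alphabet(residues, c(AA20, "X"), id)
  structure(list(id = id, residues = residues), class = "protein_record")
}

#' @rdname protein_record
#' @export
coding_record <- function(id, nucleotides, frame_offset = 0L) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(nucleotides), length(nucleotides) == 1L)
  nucleotides <- toupper(nucleotides)
  if (nchar(nucleotides) == 0L) stop("coding sequence '", id, "' is empty")
  check_alphabet(nucleotides, c("A", "C", "G", "T", "N"), id)
  if (!frame_offset %in% 0:2) stop("frame_offset must be 0, 1 or 2")
  structure(list(id = id, nucleotides = nucleotides,
                 frame_offset = as.integer(frame_offset)),
            class = "coding_record")
}

# error names the first offending symbol and its 1-based position
check_alphabet <- function(seq, allowed, id) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% allowed)
  if (length(bad)) {
    stop("invalid character '", chars[bad[1]], "' at position ", bad[1],
         " in sequence '", id, "'")
  }
  invisible(TRUE)
}

#' @export
print.protein_record <- function(x, ...) {
  cat("protein_record ", x$id, " (", nchar(x$residues), " aa)\n", sep = "")
  invisible(x)
}

#' @export
print.coding_record <- function(x, ...) {
  cat("coding_record ", x$id, " (", nchar(x$nucleotides), " bp)\n", sep = "")
  invisible(x)
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
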