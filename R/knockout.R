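#' Apply a deletion to a coding sequence
#'
#' Removes the closed interval `[start, start + length - 1]` (1-based, in
#' nucleotides) from a coding sequence, modelling a CRISPR deletion allele.
#' The input record is left untouched.
#'
#' @param cds a [coding_record()].
#' @param start 1-based first deleted base.
#' @param length number of deleted bases (0 returns the sequence unchanged).
#' @return A new [coding_record()] with `_del<start>_<length>` appended to
#'   the id (unchanged id for length 0).
#' @examples
#' apply_deletion(coding_record("x", "ATGAAACCC"), 4, 3)  # "ATGCCC"
#' @export
apply_deletion <- function(cds, start, length) {
  stopifnot(inherits(cds, "coding_record"))
  n <- nchar(cds$nucleotides)
  if (length < 0) stop("deletion length must be non-negative")
  if (length == 0) return(cds)
  if (start < 1 || start + length - 1 > n)
    stop("deletion [", start, ", ", start + length - 1,
         "] out of bounds for sequence of length ", n)
  if (length == n) stop("deletion removes the entire sequence")
  kept <- paste0(substr(cds$nucleotides, 1L, start - 1L),
                 substr(cds$nucleotides, start + length, n))
  coding_record(paste0(cds$id, "_del", start, "_", length), kept,
                frame_offset = cds$frame_offset)
}

#' Translate a coding sequence with the standard genetic code
#'
#' Translates codon by codon from the declared frame offset until the first
#' stop codon or the end of the sequence; a trailing partial codon is
#' ignored. Codons containing `N` translate to `X`. Only the standard
#' (nuclear) genetic code is used.
#'
#' @param cds a [coding_record()].
#' @return list: `protein` (translation up to but excluding the stop) and
#'   `stop_codon_index` (1-based codon position of the first stop, `NA` if
#'   none was reached).
#' @export
translate_cds <- function(cds) {
  stopifnot(inherits(cds, "coding_record"))
  s <- substr(cds$nucleotides, cds$frame_offset + 1L, nchar(cds$nucleotides))
  n_codons <- nchar(s) %/% 3L
  if (n_codons < 1L) stop("fewer than 3 frame-adjusted bases; cannot translate")
  code <- Biostrings::GENETIC_CODE
  aa <- character(0)
  stop_at <- NA_integer_
  for (k in seq_len(n_codons)) {
    codon <- substr(s, 3L * k - 2L, 3L * k)
    res <- if (grepl("N", codon, fixed = TRUE)) "X" else unname(code[codon])
    if (identical(res, "*")) { stop_at <- k; break }
    aa <- c(aa, res)
  }
  list(protein = paste(aa, collapse = ""), stop_codon_index = stop_at)
}

#' Classify the consequence of a coding deletion
#'
#' Predicts the molecular consequence of a deletion allele:
#' \itemize{
#'   \item `frameshift` — deletion length not a multiple of 3;
#'   \item `premature_stop_codon_index` — 1-based codon index (in the edited
#'     reading frame) of the first stop codon, when it falls strictly before
#'     the position where the wild-type stop is expected after the deletion
#'     (the wild-type stop codon index minus the number of whole codons
#'     removed), or when the wild type has no stop at all; `NA` otherwise;
#'   \item `predicted_lof` — loss of function predicted when the edit causes
#'     a frameshift or a premature stop.
#' }
#' The comparison rule — edited-frame codon index against the wild-type stop
#' codon index — is a declared convention; exon structure is not modelled
#' (the spliced CDS is edited directly).
#'
#' @inheritParams apply_deletion
#' @return An `edit_outcome` list with fields `deletion_start`,
#'   `deletion_length`, `frameshift`, `premature_stop_codon_index`,
#'   `predicted_lof`, plus the wild-type and edited stop indices.
#' @export
classify_edit <- function(cds, start, length) {
  wt <- translate_cds(cds)
  edited <- apply_deletion(cds, start, length)
  ed <- translate_cds(edited)
  frameshift <- (length %% 3L) != 0L
  # where the wild-type stop would land after removing length %/% 3 codons
  stop_equivalent <- wt$stop_codon_index - length %/% 3L
  premature <- !is.na(ed$stop_codon_index) &&
    (is.na(wt$stop_codon_index) || ed$stop_codon_index < stop_equivalent)
  structure(list(
    deletion_start = as.integer(start),
    deletion_length = as.integer(length),
    frameshift = frameshift,
    premature_stop_codon_index =
      if (premature) ed$stop_codon_index else NA_integer_,
    predicted_lof = frameshift || premature,
    wildtype_stop_codon_index = wt$stop_codon_index,
    edited_stop_codon_index = ed$stop_codon_index,
    edited_protein = ed$protein
  ), class = "edit_outcome")
}

#' @export
print.edit_outcome <- function(x, ...) {
  cat("edit_outcome: ", x$deletion_length, " bp deletion at ",
      x$deletion_start, "\n  frameshift: ", x$frameshift,
      "\n  premature stop codon: ",
      ifelse(is.na(x$premature_stop_codon_index), "none",
             x$premature_stop_codon_index),
      "\n  predicted loss of function: ", x$predicted_lof, "\n", sep = "")
  invisible(x)
}

#' Write an edit outcome as JSON
#'
#' @param outcome an `edit_outcome`.
#' @param path output file.
#' @export
write_edit_outcome <- function(outcome, path) {
  jsonlite::write_json(unclass(outcome)[c(
    "deletion_start", "deletion_length", "frameshift",
    "premature_stop_codon_index", "predicted_lof",
    "wildtype_stop_codon_index", "edited_stop_codon_index")],
    path, auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' Locate an oligo (sgRNA / primer) in a sequence
#'
#' Exact matching of the oligo on the forward strand and of its reverse
#' complement (a `-` strand hit), as used to place sgRNAs and genotyping
#' primers on a coding sequence.
#'
#' @param seq a [coding_record()].
#' @param oligo character, `ACGT` only.
#' @return data.frame with 1-based `position` (start of the match on the
#'   forward sequence) and `strand` (`+`/`-`); zero rows when absent.
#' @export
find_oligo_sites <- function(seq, oligo) {
  stopifnot(inherits(seq, "coding_record"))
  oligo <- toupper(oligo)
  if (!nzchar(oligo)) stop("oligo is empty")
  check_alphabet(oligo, c("A", "C", "G", "T"), "oligo")
  hits <- function(pattern) {
    p <- gregexpr(pattern, seq$nucleotides, fixed = TRUE)[[1]]
    if (p[1] == -1L) integer(0) else as.integer(p)
  }
  fwd <- hits(oligo)
  rev <- hits(revcomp(oligo))
  out <- data.frame(
    position = c(fwd, rev),
    strand = c(rep("+", length(fwd)), rep("-", length(rev))),
    stringsAsFactors = FALSE)
  out[order(out$position), , drop = FALSE]
}

#' Reverse complement of a nucleotide string
#'
#' @param x character, `ACGTN`.
#' @return character.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
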