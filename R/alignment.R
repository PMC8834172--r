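#' Global pairwise protein alignment with affine gaps
#'
#' Aligns a query protein to a reference protein with the Gotoh three-matrix
#' dynamic programme, guaranteeing an optimal-score global alignment under
#' affine gap penalties (a gap of length L costs
#' `gap_open + (L - 1) * gap_extend`). Traceback ties are broken
#' deterministically: aligned pair over gap-in-query over gap-in-reference.
#'
#' @param ref,qry [protein_record()] objects.
#' @param scheme a [scoring_scheme()]; defaults to BLOSUM62 / 10 / 1.
#' @return A `pairwise_alignment`: list with gapped rows `row_ref` and
#'   `row_qry` (equal length, `-` for gaps), the optimal `score`, the
#'   `scheme`, and the two sequence ids.
#' @examples
#' a <- protein_record("a", "MKVLAW")
#' b <- protein_record("b", "MKLAW")
#' aln <- global_align(a, b)
#' percent_identity(aln)
#' @export
global_align <- function(ref, qry, scheme = default_scoring_scheme()) {
  stopifnot(inherits(ref, "protein_record"), inherits(qry, "protein_record"),
            inherits(scheme, "scoring_scheme"))
  alphabet <- rownames(scheme$matrix)
  ra <- seq_chars(ref$residues)
  qa <- seq_chars(qry$residues)
  ri <- match(ra, alphabet)
  qi <- match(qa, alphabet)
  if (anyNA(ri)) {
    p <- which(is.na(ri))[1]
    stop("residue '", ra[p], "' at position ", p, " of '", ref$id,
         "' is not in the scoring alphabet")
  }
  if (anyNA(qi)) {
    p <- which(is.na(qi))[1]
    stop("residue '", qa[p], "' at position ", p, " of '", qry$id,
         "' is not in the scoring alphabet")
  }

  res <- .gotoh_align(ri, qi, scheme$matrix, scheme$gap_open, scheme$gap_extend)
  moves <- res$moves
  row_ref <- character(length(moves))
  row_qry <- character(length(moves))
  i <- 0L; j <- 0L
  for (k in seq_along(moves)) {
    if (moves[k] == 1L) {        # aligned pair
      i <- i + 1L; j <- j + 1L
      row_ref[k] <- ra[i]; row_qry[k] <- qa[j]
    } else if (moves[k] == 2L) { # gap in query row
      i <- i + 1L
      row_ref[k] <- ra[i]; row_qry[k] <- "-"
    } else {                     # gap in reference row
      j <- j + 1L
      row_ref[k] <- "-"; row_qry[k] <- qa[j]
    }
  }
  aln <- structure(list(row_ref = paste(row_ref, collapse = ""),
                        row_qry = paste(row_qry, collapse = ""),
                        score = res$score, scheme = scheme,
                        ref_id = ref$id, qry_id = qry$id),
                   class = "pairwise_alignment")
  # invariant: DP score equals the recomputed column-wise score
  rescored <- alignment_score(aln)
  if (abs(rescored - res$score) > 1e-6)
    stop("internal error: traceback score ", rescored,
         " disagrees with DP score ", res$score)
  aln
}

#' Recompute an alignment's score column by column
#'
#' Walks the two gapped rows, charging substitution scores for aligned pairs
#' and `gap_open + (L - 1) * gap_extend` for each gap run. Used internally as
#' a consistency check on the dynamic programme and exported for scoring
#' externally produced alignments.
#'
#' @param aln a `pairwise_alignment`.
#' @return numeric score.
#' @export
alignment_score <- function(aln) {
  r <- seq_chars(aln$row_ref)
  q <- seq_chars(aln$row_qry)
  m <- aln$scheme$matrix
  go <- aln$scheme$gap_open; ge <- aln$scheme$gap_extend
  score <- 0
  in_gap_r <- FALSE; in_gap_q <- FALSE
  for (k in seq_along(r)) {
    if (r[k] == "-" && q[k] == "-") stop("column ", k, " is gap in both rows")
    if (r[k] == "-") {
      score <- score - (if (in_gap_r) ge else go)
      in_gap_r <- TRUE; in_gap_q <- FALSE
    } else if (q[k] == "-") {
      score <- score - (if (in_gap_q) ge else go)
      in_gap_q <- TRUE; in_gap_r <- FALSE
    } else {
      score <- score + m[r[k], q[k]]
      in_gap_r <- FALSE; in_gap_q <- FALSE
    }
  }
  score
}

#' Percent identity of an alignment
#'
#' Fraction (as a percentage) of identical aligned residues. The default
#' denominator is the number of columns where the reference row holds a
#' residue, so conservation is measured over the reference protein's
#' positions; gaps and substitutions in the query both count against
#' identity. `X` never counts as identical.
#'
#' @param aln a `pairwise_alignment`.
#' @param columns optional integer vector of alignment columns to restrict to.
#' @param denominator `"reference"` (reference non-gap columns, default),
#'   `"columns"` (all selected columns), or `"shorter"` (length of the
#'   shorter sequence; only meaningful for the full alignment).
#' @return Percentage in `[0, 100]`, or `NA` when the denominator is zero
#'   (e.g. the reference is all-gap over the requested columns) — undefined
#'   identity is reported as missing, never as 0.
#' @export
percent_identity <- function(aln, columns = NULL,
                             denominator = c("reference", "columns", "shorter")) {
  denominator <- match.arg(denominator)
  r <- seq_chars(aln$row_ref)
  q <- seq_chars(aln$row_qry)
  if (!is.null(columns)) {
    if (any(columns < 1L | columns > length(r)))
      stop("columns out of range 1..", length(r))
    r <- r[columns]; q <- q[columns]
  }
  ident <- sum(r == q & r != "-" & r != "X")
  denom <- switch(denominator,
                  reference = sum(r != "-"),
                  columns = length(r),
                  shorter = min(nchar(gsub("-", "", aln$row_ref, fixed = TRUE)),
                                nchar(gsub("-", "", aln$row_qry, fixed = TRUE))))
  if (denom == 0L) return(NA_real_)
  100 * ident / denom
}

#' Map reference residue positions to alignment columns
#'
#' `map_ref_position_to_column()` returns the alignment column holding the
#' `ref_pos`-th residue of the (gapped) reference row;
#' `map_column_to_ref_position()` is its inverse for reference-residue
#' columns. These bridge reference-coordinate domain annotations onto the
#' alignment.
#'
#' @param aln a `pairwise_alignment`.
#' @param ref_pos 1-based residue index (vectorised).
#' @param column 1-based alignment column (vectorised).
#' @return integer column indices / residue positions.
#' @export
map_ref_position_to_column <- function(aln, ref_pos) {
  r <- seq_chars(aln$row_ref)
  cols <- which(r != "-")
  if (any(ref_pos < 1L | ref_pos > length(cols)))
    stop("ref_pos out of range 1..", length(cols))
  cols[ref_pos]
}

#' @rdname map_ref_position_to_column
#' @export
map_column_to_ref_position <- function(aln, column) {
  r <- seq_chars(aln$row_ref)
  if (any(column < 1L | column > length(r)))
    stop("column out of range 1..", length(r))
  if (any(r[column] == "-"))
    stop("column holds a reference gap; no residue position")
  cumsum(r != "-")[column]
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("pairwise_alignment ", x$ref_id, " vs ", x$qry_id,
      " (", nchar(x$row_ref), " columns, score ", x$score, ")\n", sep = "")
  invisible(x)
}

#' Write an alignment as aligned FASTA
#'
#' @param aln a `pairwise_alignment`.
#' @param path output file.
#' @export
write_alignment_fasta <- function(aln, path) {
  ss <- Biostrings::BStringSet(stats::setNames(c(aln$row_ref, aln$row_qry),
                                               c(aln$ref_id, aln$qry_id)))
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

# degapped reference row (used to verify two alignments share a reference)
alignment_reference <- function(aln) gsub("-", "", aln$row_ref, fixed = TRUE)
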