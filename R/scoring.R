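#' Substitution scoring schemes
#'
#' A scoring scheme bundles a symmetric substitution matrix (integer scores
#' over the 20 canonical residues plus `X`) with non-negative affine gap
#' penalties. A gap of length L costs `gap_open + (L - 1) * gap_extend`.
#'
#' The default scheme is BLOSUM62 with gap open 10 and gap extend 1
#' (EMBOSS-style defaults for global protein alignment).
#'
#' @param matrix square numeric matrix with identical row/column names
#'   giving the alphabet.
#' @param gap_open,gap_extend non-negative penalties, `gap_extend <= gap_open`.
#' @return A `scoring_scheme` object.
#' @examples
#' sc <- default_scoring_scheme()
#' sc$matrix["A", "A"]
#' @export
scoring_scheme <- function(matrix, gap_open = 10, gap_extend = 1) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  if (is.null(rownames(matrix)) || !identical(rownames(matrix), colnames(matrix)))
    stop("substitution matrix must have identical row and column names")
  if (!isTRUE(all.equal(matrix, t(matrix))))
    stop("substitution matrix must be symmetric")
  if (gap_open < 0 || gap_extend < 0)
    stop("gap penalties must be non-negative")
  if (gap_extend > gap_open)
    stop("gap_extend must not exceed gap_open")
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "scoring_scheme")
}

#' @rdname scoring_scheme
#' @export
default_scoring_scheme <- function(gap_open = 10, gap_extend = 1) {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  m <- env$BLOSUM62
  keep <- c(AA20, "X")
  scoring_scheme(m[keep, keep], gap_open, gap_extend)
}

#' Read an NCBI-format substitution matrix
#'
#' Parses the plain-text matrix format used by NCBI/EMBOSS (comment lines
#' starting with `#`, a header row of residues, then one labelled row per
#' residue). The asymmetric `*` column, if present, is dropped.
#'
#' @param path file path.
#' @param gap_open,gap_extend penalties for the returned scheme.
#' @return A [scoring_scheme()].
#' @export
read_scoring_matrix <- function(path, gap_open = 10, gap_extend = 1) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("not a matrix file: ", path)
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  labels <- vapply(rows, `[`, "", 1L)
  vals <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(length(header))))
  dimnames(vals) <- list(labels, header)
  keep <- setdiff(intersect(rownames(vals), colnames(vals)), "*")
  scoring_scheme(vals[keep, keep], gap_open, gap_extend)
}
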