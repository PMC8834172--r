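#' Domain annotation tables
#'
#' A domain annotation names a feature of the reference protein — a
#' transmembrane segment, extracellular loop, cytoplasmic linker, pore
#' loop, or terminus — by a 1-based inclusive coordinate span, following
#' the UniProt feature convention for voltage-gated sodium channels
#' (domains I-IV, segments S1-S6). Spans must be non-overlapping, within
#' the reference, and carry unique labels. Features shorter than
#' `short_peptide_below` residues are marked `short_peptide` (the asterisk
#' convention: identity over a handful of residues is noisy).
#'
#' @param domains data.frame with columns `label`, `class`,
#'   `channel_domain` (I-IV or NA), `start`, `end`.
#' @param ref_length optional reference length for bounds checking.
#' @param short_peptide_below spans shorter than this many residues are
#'   flagged as short peptides (default 5).
#' @return The validated data.frame, sorted by `start`, with a
#'   `short_peptide` logical column added.
#' @export
domain_annotations <- function(domains, ref_length = NULL,
                               short_peptide_below = 5L) {
  req <- c("label", "class", "start", "end")
  miss <- setdiff(req, names(domains))
  if (length(miss)) stop("domain table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!"channel_domain" %in% names(domains)) domains$channel_domain <- NA
  domains$start <- as.integer(domains$start)
  domains$end <- as.integer(domains$end)
  bad <- which(is.na(domains$start) | is.na(domains$end) |
                 domains$start < 1L | domains$end < domains$start)
  if (length(bad))
    stop("invalid span in domain row(s): ",
         paste(domains$label[bad], collapse = ", "))
  if (!is.null(ref_length)) {
    oob <- which(domains$end > ref_length)
    if (length(oob))
      stop("span beyond reference length ", ref_length, " in row(s): ",
           paste(domains$label[oob], collapse = ", "))
  }
  if (anyDuplicated(domains$label))
    stop("duplicate domain label(s): ",
         paste(unique(domains$label[duplicated(domains$label)]), collapse = ", "))
  unknown <- setdiff(unique(domains$class), DOMAIN_CLASSES)
  if (length(unknown))
    stop("unknown domain class(es): ", paste(unknown, collapse = ", "))
  domains <- domains[order(domains$start), , drop = FALSE]
  ov <- which(domains$start[-1] <= domains$end[-nrow(domains)])
  if (length(ov))
    stop("overlapping domain span(s): ",
         paste(paste(domains$label[ov], domains$label[ov + 1L], sep = "/"),
               collapse = ", "))
  domains$short_peptide <- (domains$end - domains$start + 1L) < short_peptide_below
  rownames(domains) <- NULL
  domains
}

#' Read / write a domain annotation table (TSV)
#'
#' The table dialect is tab-separated with a header row
#' `label class channel_domain start end`. `read_domain_gff()` additionally
#' imports UniProt-style feature GFF rows of type `Topological domain` or
#' `Transmembrane` (1-based inclusive coordinates pass straight through).
#'
#' @param path file path.
#' @inheritParams domain_annotations
#' @return A validated annotation data.frame (see [domain_annotations()]).
#' @export
read_domain_table <- function(path, ref_length = NULL, short_peptide_below = 5L) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  domain_annotations(df, ref_length = ref_length,
                     short_peptide_below = short_peptide_below)
}

#' @rdname read_domain_table
#' @param domains validated annotation data.frame.
#' @export
write_domain_table <- function(domains, path) {
  utils::write.table(domains[, c("label", "class", "channel_domain",
                                 "start", "end")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_domain_table
#' @export
read_domain_gff <- function(path, ref_length = NULL, short_peptide_below = 5L) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(f, function(x) length(x) >= 5 &&
                   x[3] %in% c("Topological domain", "Transmembrane"), TRUE)
  f <- f[keep]
  if (!length(f)) stop("no Topological domain / Transmembrane rows in ", path)
  note <- vapply(f, function(x) {
    if (length(x) >= 9 && grepl("Note=", x[9]))
      sub(";.*$", "", sub(".*Note=", "", x[9])) else x[3]
  }, "")
  df <- data.frame(
    label = make.unique(note),
    class = ifelse(vapply(f, `[`, "", 3) == "Transmembrane",
                   "TM_segment", "other"),
    channel_domain = NA,
    start = as.integer(vapply(f, `[`, "", 4)),
    end = as.integer(vapply(f, `[`, "", 5)),
    stringsAsFactors = FALSE)
  domain_annotations(df, ref_length = ref_length,
                     short_peptide_below = short_peptide_below)
}

#' Per-domain conservation scoring of two paralogs against one reference
#'
#' The core comparison: each reference domain span is projected through both
#' alignments (via [map_ref_position_to_column()]), percent identity is
#' computed over the projected columns for each paralog, and the difference
#' `delta = identity_b - identity_a` (percentage points; positive means
#' paralog B is better conserved) is tested against the differential-
#' conservation threshold. Flagging is strict: a domain is flagged when
#' `|delta|` exceeds — not equals — the threshold (default 20 points).
#' Domains whose reference span aligns entirely to gaps in a paralog get
#' `NA` identity and are never flagged.
#'
#' @param aln_a,aln_b `pairwise_alignment`s of paralog A and paralog B
#'   against the *same* reference sequence.
#' @param domains validated annotation data.frame ([domain_annotations()]).
#' @param threshold flag threshold in percentage points (default 20).
#' @return data.frame: the annotation columns plus `identity_a`,
#'   `identity_b`, `delta` and `flagged`, one row per domain in input order.
#' @export
score_domains <- function(aln_a, aln_b, domains, threshold = 20) {
  if (!identical(alignment_reference(aln_a), alignment_reference(aln_b)))
    stop("the two alignments do not share the same reference sequence")
  ident <- function(aln, start, end) {
    cols <- map_ref_position_to_column(aln, start):map_ref_position_to_column(aln, end)
    percent_identity(aln, columns = cols)
  }
  ia <- mapply(ident, start = domains$start, end = domains$end,
               MoreArgs = list(aln = aln_a))
  ib <- mapply(ident, start = domains$start, end = domains$end,
               MoreArgs = list(aln = aln_b))
  delta <- ib - ia
  out <- domains
  out$identity_a <- ia
  out$identity_b <- ib
  out$delta <- delta
  out$flagged <- !is.na(delta) & abs(delta) > threshold
  out
}

#' Protein-wide identity of one paralog versus the reference
#'
#' [percent_identity()] over the full alignment — the single-number summary
#' of paralog conservation. Full precision is returned; round to integer
#' for display.
#'
#' @param aln a `pairwise_alignment`.
#' @return percentage.
#' @export
proteinwide_identity <- function(aln) percent_identity(aln)

#' Write / read a conservation report
#'
#' TSV with columns `label class channel_domain start end identity_a
#' identity_b delta flagged short_peptide` plus a one-line summary of total
#' and flagged domain counts.
#'
#' @param records output of [score_domains()].
#' @param path TSV output path.
#' @param summary_path optional path for the text summary; `NULL` skips it.
#' @return The summary line, invisibly.
#' @export
write_conservation_report <- function(records, path, summary_path = NULL,
                                      threshold = 20) {
  if (!nrow(records)) stop("empty record list")
  cols <- c("label", "class", "channel_domain", "start", "end",
            "identity_a", "identity_b", "delta", "flagged", "short_peptide")
  utils::write.table(records[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summary <- sprintf("%d domains scored, %d flagged (>%s point difference)",
                     nrow(records), sum(records$flagged, na.rm = TRUE),
                     format(threshold))
  if (!is.null(summary_path)) writeLines(summary, summary_path)
  invisible(summary)
}

#' @rdname write_conservation_report
#' @export
read_conservation_report <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
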