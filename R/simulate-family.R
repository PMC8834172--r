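#' Specification of a synthetic paralog family
#'
#' Defines a reference protein with a domain architecture and two paralogs
#' diverged from it at controlled per-site substitution rates: each domain
#' carries its own rate for paralog A and paralog B, residues outside any
#' domain diverge at `inter_domain_divergence`. The substitution model
#' replaces a residue, with the site's probability, by a uniformly chosen
#' *different* residue, so the expected realized identity of a region with
#' rate `d` is exactly `1 - d`.
#'
#' Optional small indels (1-3 residues, per-site probability `indel_rate`,
#' default off) are placed only outside truth-flagged domains so the
#' divergence ground truth stays well-defined.
#'
#' @param ref_length reference residue count.
#' @param domains data.frame with columns `label`, `class`,
#'   `channel_domain`, `start`, `end`, `divergence_a`, `divergence_b`
#'   (per-site substitution probabilities in `[0, 1]`).
#' @param inter_domain_divergence per-site rate outside all domains.
#' @param indel_rate per-site probability of a 1-3 residue indel (default 0).
#' @param flag_threshold domains whose `|divergence_a - divergence_b|`
#'   exceeds this are the truth-flagged set (default 0.20).
#' @param seed integer seed; the same spec and seed reproduce the family
#'   byte-identically.
#' @return A `paralog_family_spec` object.
#' @export
paralog_family_spec <- function(ref_length, domains,
                                inter_domain_divergence = 0.05,
                                indel_rate = 0, flag_threshold = 0.20,
                                seed = 1L) {
  stopifnot(ref_length >= 1)
  probs <- c(domains$divergence_a, domains$divergence_b,
             inter_domain_divergence, indel_rate)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1))
    stop("all divergence/indel probabilities must be in [0, 1]")
  domains <- domain_annotations(domains, ref_length = ref_length)
  structure(list(ref_length = as.integer(ref_length), domains = domains,
                 inter_domain_divergence = inter_domain_divergence,
                 indel_rate = indel_rate, flag_threshold = flag_threshold,
                 seed = as.integer(seed)),
            class = "paralog_family_spec")
}

#' Simulate a reference protein and two diverged paralogs
#'
#' Draws the reference uniformly over the 20 canonical residues, derives
#' each paralog site-wise under the spec's substitution model, and records
#' the ground truth: the annotations and the labels of domains whose
#' divergence-rate difference between the paralogs exceeds the flag
#' threshold — the set a correct conservation analysis should recover.
#'
#' @param spec a [paralog_family_spec()].
#' @return A `family_truth` list: `reference`, `paralog_a`, `paralog_b`
#'   ([protein_record()]s), `annotations`, `expected_flagged` (character
#'   labels) and the `spec`.
#' @export
simulate_paralog_family <- function(spec) {
  stopifnot(inherits(spec, "paralog_family_spec"))
  set.seed(spec$seed)
  L <- spec$ref_length
  ref <- sample(AA20, L, replace = TRUE)

  d_a <- rep(spec$inter_domain_divergence, L)
  d_b <- rep(spec$inter_domain_divergence, L)
  for (r in seq_len(nrow(spec$domains))) {
    idx <- spec$domains$start[r]:spec$domains$end[r]
    d_a[idx] <- spec$domains$divergence_a[r]
    d_b[idx] <- spec$domains$divergence_b[r]
  }

  mutate <- function(rates) {
    hit <- runif(L) < rates
    out <- ref
    n <- sum(hit)
    if (n) {
      # shift by 1..19 positions in the alphabet: uniform over the 19
      # alternatives, never the original residue
      shift <- sample.int(19L, n, replace = TRUE)
      out[hit] <- AA20[((match(ref[hit], AA20) - 1L + shift) %% 20L) + 1L]
    }
    out
  }
  pa <- mutate(d_a)
  pb <- mutate(d_b)

  if (spec$indel_rate > 0) {
    pa <- apply_indels(pa, spec)
    pb <- apply_indels(pb, spec)
  }

  delta <- abs(spec$domains$divergence_a - spec$domains$divergence_b)
  structure(list(
    reference = protein_record("reference", paste(ref, collapse = "")),
    paralog_a = protein_record("paralog_a", paste(pa, collapse = "")),
    paralog_b = protein_record("paralog_b", paste(pb, collapse = "")),
    annotations = spec$domains,
    expected_flagged = spec$domains$label[delta > spec$flag_threshold],
    spec = spec
  ), class = "family_truth")
}

# 1-3 residue insertions/deletions at sites outside truth-flagged domains
apply_indels <- function(chars, spec) {
  delta <- abs(spec$domains$divergence_a - spec$domains$divergence_b)
  flagged <- spec$domains[delta > spec$flag_threshold, , drop = FALSE]
  allowed <- rep(TRUE, length(chars))
  for (r in seq_len(nrow(flagged)))
    allowed[flagged$start[r]:flagged$end[r]] <- FALSE
  sites <- which(allowed & runif(length(chars)) < spec$indel_rate)
  for (s in rev(sites)) {           # right-to-left keeps coordinates valid
    len <- sample.int(3L, 1L)
    if (runif(1) < 0.5) {
      keep <- setdiff(seq_along(chars), s:min(s + len - 1L, length(chars)))
      chars <- chars[keep]
    } else {
      chars <- append(chars, sample(AA20, len, replace = TRUE), after = s)
    }
  }
  chars
}

#' Sodium-channel-like family architecture
#'
#' The default study conditions for the synthetic genotype pipeline: a
#' reference protein with the canonical voltage-gated sodium-channel
#' architecture — N-terminus, four homologous channel domains (I-IV) each
#' holding six transmembrane segments S1-S6 with their extracellular loops,
#' cytoplasmic S2-S3 / S4-S5 linkers and a three-part pore region, three
#' cytoplasmic inter-domain linkers plus the short IFM inactivation motif,
#' and a C-terminus — 58 annotated features over 1750 residues.
#'
#' Divergence rates model a teleost ohnolog pair versus the single human
#' ortholog: paralog B diverges at 0.23 per site everywhere (protein-wide
#' expected identity 77%); paralog A matches it except in 12 differentially
#' conserved domains (among them the domain-II S4 voltage sensor and a
#' domain-IV cytoplasmic linker) where its rate is 0.45 higher, giving a
#' protein-wide expected identity of 67%.
#'
#' @param seed integer seed.
#' @param divergence_b baseline per-site divergence of both paralogs.
#' @param flag_extra extra divergence of paralog A inside the 12
#'   differentially conserved domains.
#' @param drift_extra extra divergence of paralog A elsewhere (keeps the
#'   two paralogs from being identical outside the flagged set).
#' @return A [paralog_family_spec()].
#' @export
channel_family_spec <- function(seed = 1L, divergence_b = 0.23,
                                flag_extra = 0.47, drift_extra = 0.02) {
  feat <- list()
  pos <- 0L
  add <- function(label, klass, len, cd = NA) {
    feat[[length(feat) + 1L]] <<- data.frame(
      label = label, class = klass, channel_domain = cd,
      start = pos + 1L, end = pos + len, stringsAsFactors = FALSE)
    pos <<- pos + len
  }
  add("N-terminus", "N_terminus", 130L)
  roman <- c("I", "II", "III", "IV")
  for (d in roman) {
    add(paste0("D", d, "-S1"), "TM_segment", 22L, d)
    add(paste0("D", d, "-S1S2"), "extracellular_loop", 28L, d)
    add(paste0("D", d, "-S2"), "TM_segment", 22L, d)
    add(paste0("D", d, "-S2S3"), "cytoplasmic_linker", 25L, d)
    add(paste0("D", d, "-S3"), "TM_segment", 22L, d)
    add(paste0("D", d, "-S3S4"), "extracellular_loop", 18L, d)
    add(paste0("D", d, "-S4"), "TM_segment", 22L, d)
    add(paste0("D", d, "-S4S5"), "cytoplasmic_linker", 25L, d)
    add(paste0("D", d, "-S5"), "TM_segment", 22L, d)
    add(paste0("D", d, "-pore-desc"), "pore_loop", 30L, d)
    add(paste0("D", d, "-pore-helix"), "pore_loop", 4L, d)
    add(paste0("D", d, "-pore-asc"), "pore_loop", 30L, d)
    add(paste0("D", d, "-S6"), "TM_segment", 22L, d)
    if (d == "I") add("linker-I-II", "cytoplasmic_linker", 300L)
    if (d == "II") add("linker-II-III", "cytoplasmic_linker", 240L)
    if (d == "III") {
      add("linker-III-IV", "cytoplasmic_linker", 45L)
      add("IFM-motif", "cytoplasmic_linker", 3L)
    }
  }
  add("C-terminus", "C_terminus", 330L)
  domains <- do.call(rbind, feat)

  # the 12 differentially conserved features: spread over TM segments,
  # loops, cytoplasmic linkers and the N-terminus, including the DII voltage
  # sensor and a DIV cytoplasmic linker
  flagged <- c("N-terminus", "DI-S1S2", "DI-S2S3", "DI-S3",
               "DII-S1S2", "DII-S2S3", "DII-S4",
               "DIII-S1", "DIII-S3S4", "DIII-S4S5",
               "DIV-S2S3", "DIV-S5")
  domains$divergence_b <- divergence_b
  domains$divergence_a <- divergence_b + drift_extra +
    ifelse(domains$label %in% flagged, flag_extra - drift_extra, 0)
  paralog_family_spec(ref_length = pos, domains = domains,
                      inter_domain_divergence = divergence_b,
                      seed = seed)
}

#' Write a simulated family to disk
#'
#' FASTA for the three sequences, TSV for the annotations, and a one-column
#' truth table of expected-flagged labels.
#'
#' @param family a `family_truth` from [simulate_paralog_family()].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_family <- function(family, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(family$reference, file.path(dir, "reference.fasta"))
  write_fasta(family$paralog_a, file.path(dir, "paralog_a.fasta"))
  write_fasta(family$paralog_b, file.path(dir, "paralog_b.fasta"))
  write_domain_table(family$annotations, file.path(dir, "domains.tsv"))
  writeLines(family$expected_flagged, file.path(dir, "expected_flagged.txt"))
  invisible(dir)
}
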