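#' Synthetic knockout-allele coding sequence
#'
#' A deterministic, fully synthetic stand-in for the edited sodium-channel
#' coding sequence: a short CDS that embeds the published sgRNA
#' protospacer (GATGAGGTTCACCAGGTAGA) and the two genotyping primer sites
#' (forward primer on the + strand upstream, reverse primer as a - strand
#' match downstream), translates cleanly to its final stop in the wild
#' type, and is engineered so that the recommended 7 bp deletion at the
#' sgRNA cut site shifts the frame into a stop codon within a few codons —
#' the same frameshift / premature-stop structure as the real allele,
#' whose exact deleted bases are not machine-readable from the published
#' trace.
#'
#' @return list: `cds` (a [coding_record()]), `del_start`, `del_len` (7),
#'   `sgrna`, `primer_fw`, `primer_rv`.
#' @examples
#' fix <- synthetic_knockout_cds()
#' classify_edit(fix$cds, fix$del_start, fix$del_len)
#' @export
synthetic_knockout_cds <- function() {
  sgrna <- "GATGAGGTTCACCAGGTAGA"
  primer_fw <- "TTTGATCCAATCCCTTATCC"
  primer_rv <- "CAACAGACCTCAGCTTCCTG"
  # 108 bp: ATG, forward primer, filler, protospacer (position 43), filler,
  # reverse-complemented reverse primer, terminal TAA. The wild type
  # translates to its terminal stop (codon 36); deleting 7 bp at position
  # 53 (inside the protospacer) shifts the frame into a stop at codon 20.
  seq <- paste0(
    "ATG", primer_fw, "A",
    "GGTCACCTGGAGCTGACC",
    sgrna, "G", "GTA",
    "GCTGAAGCTTGGCACTGG",
    revcomp(primer_rv), "C",
    "TAA")
  list(cds = coding_record("synthetic_scn1laa_like_cds", seq),
       del_start = 53L, del_len = 7L,
       sgrna = sgrna, primer_fw = primer_fw, primer_rv = primer_rv)
}
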