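test_that("domain tables are validated, ordered and short-peptide marked", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("label\tclass\tchannel_domain\tstart\tend",
               "B\tTM_segment\tI\t20\t39",
               "A\tN_terminus\tNA\t1\t10",
               "C\tpore_loop\tI\t45\t48"), path)
  doms <- read_domain_table(path, ref_length = 60)
  expect_equal(doms$label, c("A", "B", "C"))          # sorted by start
  expect_equal(doms$short_peptide, c(FALSE, FALSE, TRUE))

  writeLines(c("label\tclass\tchannel_domain\tstart\tend",
               "bad\tTM_segment\tI\t30\t20"), path)
  expect_error(read_domain_table(path), "bad")

  writeLines(c("label\tclass\tchannel_domain\tstart\tend",
               "x\tTM_segment\tI\t1\t30",
               "y\tTM_segment\tI\t25\t40"), path)
  expect_error(read_domain_table(path), "overlap")

  writeLines(c("label\tclass\tchannel_domain\tstart\tend",
               "far\tTM_segment\tI\t50\t90"), path)
  expect_error(read_domain_table(path, ref_length = 60), "beyond reference")
})

test_that("identical paralogs score 100 everywhere with no flags", {
  fam <- simulate_paralog_family(
    recovery_family_spec(seed = 3, d_base = 0, d_flag = 0, drift = 0))
  aln_a <- global_align(fam$reference, fam$paralog_a)
  aln_b <- global_align(fam$reference, fam$paralog_b)
  rec <- score_domains(aln_a, aln_b, fam$annotations)
  expect_true(all(rec$identity_a == 100))
  expect_true(all(rec$identity_b == 100))
  expect_false(any(rec$flagged))
  expect_equal(proteinwide_identity(aln_a), 100)
})

test_that("a strongly differentially conserved domain is flagged", {
  fam <- simulate_paralog_family(recovery_family_spec(seed = 21))
  aln_a <- global_align(fam$reference, fam$paralog_a)
  aln_b <- global_align(fam$reference, fam$paralog_b)
  rec <- score_domains(aln_a, aln_b, fam$annotations)
  expect_identical(rec$label[rec$flagged], "dom2")
  expect_identical(fam$expected_flagged, "dom2")
  # sign convention: paralog B better conserved => positive delta
  expect_gt(rec$delta[rec$label == "dom2"], 0)
})

test_that("flagging uses a strict inequality at the 20-point threshold", {
  # engineered alignments: 10-residue domain, identity_a 70%, identity_b 90%
  ref <- "AAAAAAAAAA"
  qa <- "CCCAAAAAAA"   # 7/10
  qb <- "CAAAAAAAAA"   # 9/10
  sc <- default_scoring_scheme()
  aln_a <- manual_alignment(ref, qa, sc)
  aln_b <- manual_alignment(ref, qb, sc)
  doms <- domain_annotations(data.frame(
    label = "d", class = "other", channel_domain = NA, start = 1, end = 10))
  rec <- score_domains(aln_a, aln_b, doms)
  expect_equal(rec$delta, 20)
  expect_false(rec$flagged)                 # exactly 20 is NOT flagged
  # one more point of difference flips it
  rec2 <- score_domains(aln_a, manual_alignment(ref, "AAAAAAAAAA", sc), doms)
  expect_equal(rec2$delta, 30)
  expect_true(rec2$flagged)
})

test_that("reference-gap domains are undefined and never flagged", {
  sc <- default_scoring_scheme()
  aln_a <- manual_alignment("AC---D", "ACTTTD", sc)
  aln_b <- manual_alignment("AC---D", "ACGGGD", sc)
  doms <- domain_annotations(data.frame(
    label = c("head", "tail"), class = "other", channel_domain = NA,
    start = c(1, 3), end = c(2, 3)))
  # domain "tail" covers reference residue 3 = column 6 ('D'): defined;
  # but restricting to the inserted columns only is undefined
  expect_true(is.na(percent_identity(aln_a, columns = 3:5)))
  rec <- score_domains(aln_a, aln_b, doms)
  expect_false(any(is.na(rec$identity_a)))
})

test_that("alignments over different references are refused", {
  a <- global_align(protein_record("r1", "MKVLAW"), protein_record("q", "MKVLAW"))
  b <- global_align(protein_record("r2", "MKVLAY"), protein_record("q", "MKVLAW"))
  expect_error(score_domains(a, b, domain_annotations(data.frame(
    label = "d", class = "other", channel_domain = NA, start = 1, end = 3))),
    "same reference")
})

test_that("domain match counts partition the protein-wide match count", {
  fam <- simulate_paralog_family(recovery_family_spec(seed = 31))
  # cover the whole reference with contiguous domains
  L <- nchar(fam$reference$residues)
  edges <- unique(c(seq(1, L, by = 50), L + 1))
  doms <- domain_annotations(data.frame(
    label = paste0("w", seq_len(length(edges) - 1)),
    class = "other", channel_domain = NA,
    start = head(edges, -1), end = tail(edges, -1) - 1))
  aln <- global_align(fam$reference, fam$paralog_a)
  per_domain <- vapply(seq_len(nrow(doms)), function(i) {
    cols <- map_ref_position_to_column(aln, doms$start[i]):
      map_ref_position_to_column(aln, doms$end[i])
    n_ref <- sum(strsplit(aln$row_ref, "")[[1]][cols] != "-")
    percent_identity(aln, cols) * n_ref / 100
  }, 0)
  total <- percent_identity(aln) * L / 100
  expect_equal(sum(per_domain), total, tolerance = 1e-9)
})

test_that("conservation reports round-trip through TSV", {
  fam <- simulate_paralog_family(recovery_family_spec(seed = 41))
  aln_a <- global_align(fam$reference, fam$paralog_a)
  aln_b <- global_align(fam$reference, fam$paralog_b)
  rec <- score_domains(aln_a, aln_b, fam$annotations)
  path <- tempfile(fileext = ".tsv"); spath <- tempfile()
  msg <- write_conservation_report(rec, path, spath)
  expect_match(msg, "4 domains scored, 1 flagged")
  back <- read_conservation_report(path)
  expect_equal(nrow(back), nrow(rec))
  expect_equal(back$identity_a, rec$identity_a, tolerance = 1e-9)
  expect_equal(back$flagged, rec$flagged)
  expect_error(write_conservation_report(rec[0, ], tempfile()), "empty")
})

test_that("increasing divergence never increases expected identity", {
  ds <- c(0.1, 0.3, 0.5)
  means <- vapply(ds, function(d) {
    mean(vapply(1:20, function(s) {
      dom <- data.frame(label = "d", class = "other", channel_domain = NA,
                        start = 1L, end = 300L,
                        divergence_a = d, divergence_b = 0)
      fam <- simulate_paralog_family(
        paralog_family_spec(300L, dom, inter_domain_divergence = 0, seed = s))
      aln <- global_align(fam$reference, fam$paralog_a)
      percent_identity(aln)
    }, 0))
  }, 0)
  expect_true(all(diff(means) < 0))
})

test_that("UniProt feature GFF rows import as domains", {
  path <- tempfile(fileext = ".gff")
  writeLines(c("##gff-version 3",
               paste("P35498", "UniProtKB", "Transmembrane", "130", "152",
                     ".", ".", ".", "Note=Helical;evidence=x", sep = "\t"),
               paste("P35498", "UniProtKB", "Topological domain", "1", "129",
                     ".", ".", ".", "Note=Cytoplasmic", sep = "\t")), path)
  doms <- read_domain_gff(path)
  expect_equal(nrow(doms), 2)
  expect_equal(doms$class, c("other", "TM_segment"))
  expect_equal(doms$start, c(1L, 130L))
})
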