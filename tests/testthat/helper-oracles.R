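# Independent oracles used by the tests. These deliberately avoid the
# package's dynamic-programming code paths.

# Brute-force global alignment: explore every sequence of moves
# (pair / ref-gap / qry-gap), charging gap_open for the first residue of a
# gap run and gap_extend for each further one, and return the maximum
# total score over all complete alignments.
brute_force_align_score <- function(a, b, mat, gap_open, gap_extend) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  la <- length(a); lb <- length(b)
  rec <- function(i, j, prev) {
    if (i == la && j == lb) return(0)
    best <- -Inf
    if (i < la && j < lb) {
      s <- mat[a[i + 1], b[j + 1]] + rec(i + 1, j + 1, "M")
      if (s > best) best <- s
    }
    if (i < la) {
      cost <- if (prev == "X") gap_extend else gap_open
      s <- -cost + rec(i + 1, j, "X")
      if (s > best) best <- s
    }
    if (j < lb) {
      cost <- if (prev == "Y") gap_extend else gap_open
      s <- -cost + rec(i, j + 1, "Y")
      if (s > best) best <- s
    }
    best
  }
  rec(0, 0, "start")
}

# random symmetric integer matrix over a 3-letter (amino-acid) alphabet
random_toy_scheme <- function() {
  ab <- c("A", "C", "D")
  m <- matrix(sample(-4:8, 9, replace = TRUE), 3, 3,
              dimnames = list(ab, ab))
  m <- (m + t(m)) %/% 2
  diag(m) <- abs(diag(m)) + 1          # favour matches a little
  go <- sample(2:8, 1)
  ge <- sample(0:go, 1)
  scoring_scheme(m, gap_open = go, gap_extend = ge)
}

random_toy_seq <- function(max_len = 6) {
  n <- sample(1:max_len, 1)
  paste(sample(c("A", "C", "D"), n, replace = TRUE), collapse = "")
}

# build a pairwise_alignment by hand from two gapped rows
manual_alignment <- function(row_ref, row_qry,
                             scheme = default_scoring_scheme()) {
  structure(list(row_ref = row_ref, row_qry = row_qry,
                 score = NA_real_, scheme = scheme,
                 ref_id = "ref", qry_id = "qry"),
            class = "pairwise_alignment")
}

# a small synthetic family spec for recovery tests: long domains, one
# strongly differentially conserved
recovery_family_spec <- function(seed, n_domains = 4, domain_len = 160,
                                 flagged_idx = 2, d_base = 0.05,
                                 d_flag = 0.45, drift = 0.03) {
  gap <- 20L
  starts <- gap + (seq_len(n_domains) - 1L) * (domain_len + gap) + 1L
  domains <- data.frame(
    label = paste0("dom", seq_len(n_domains)),
    class = "other", channel_domain = NA,
    start = starts, end = starts + domain_len - 1L,
    divergence_a = ifelse(seq_len(n_domains) %in% flagged_idx,
                          d_flag, d_base + drift),
    divergence_b = d_base,
    stringsAsFactors = FALSE)
  paralog_family_spec(
    ref_length = max(domains$end) + gap,
    domains = domains, inter_domain_divergence = d_base, seed = seed)
}
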