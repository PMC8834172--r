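test_that("zero divergence reproduces the reference; forced divergence never matches", {
  spec0 <- recovery_family_spec(seed = 1, d_base = 0, d_flag = 0, drift = 0)
  fam0 <- simulate_paralog_family(spec0)
  expect_identical(fam0$reference$residues, fam0$paralog_a$residues)
  expect_identical(fam0$reference$residues, fam0$paralog_b$residues)
  expect_length(fam0$expected_flagged, 0)

  # divergence 1 in one domain: every site substituted by a different residue
  spec1 <- recovery_family_spec(seed = 2, d_base = 0, d_flag = 1, drift = 0)
  fam1 <- simulate_paralog_family(spec1)
  dom <- fam1$annotations[fam1$annotations$label == "dom2", ]
  ref <- substr(fam1$reference$residues, dom$start, dom$end)
  mut <- substr(fam1$paralog_a$residues, dom$start, dom$end)
  expect_true(all(strsplit(ref, "")[[1]] != strsplit(mut, "")[[1]]))
  expect_identical(fam1$expected_flagged, "dom2")
})

test_that("identical seed and spec give byte-identical families", {
  f1 <- simulate_paralog_family(recovery_family_spec(seed = 99))
  f2 <- simulate_paralog_family(recovery_family_spec(seed = 99))
  expect_identical(f1$reference$residues, f2$reference$residues)
  expect_identical(f1$paralog_a$residues, f2$paralog_a$residues)
  expect_identical(f1$paralog_b$residues, f2$paralog_b$residues)
})

test_that("realized identity follows the binomial substitution model", {
  # one 200-site domain at divergence 0.3 over replicate seeds: the mean
  # realized identity must sit within 3 SE of binomial(200, 0.7)
  n_rep <- 100; len <- 200; d <- 0.3
  ident <- vapply(seq_len(n_rep), function(s) {
    dom <- data.frame(label = "d", class = "other", channel_domain = NA,
                      start = 1L, end = len,
                      divergence_a = d, divergence_b = 0)
    fam <- simulate_paralog_family(
      paralog_family_spec(len, dom, inter_domain_divergence = 0, seed = s))
    mean(strsplit(fam$reference$residues, "")[[1]] ==
           strsplit(fam$paralog_a$residues, "")[[1]])
  }, 0)
  se <- sqrt(d * (1 - d) / len / n_rep)
  expect_lt(abs(mean(ident) - 0.7), 3 * se)
})

test_that("realized identity converges to 1 - d for a long domain", {
  len <- 10000L
  dom <- data.frame(label = "d", class = "other", channel_domain = NA,
                    start = 1L, end = len,
                    divergence_a = 0.3, divergence_b = 0.3)
  fam <- simulate_paralog_family(
    paralog_family_spec(len, dom, inter_domain_divergence = 0, seed = 5))
  ident <- mean(strsplit(fam$reference$residues, "")[[1]] ==
                  strsplit(fam$paralog_a$residues, "")[[1]])
  expect_lt(abs(ident - 0.7), 0.01)
})

test_that("overlapping domain specs are rejected", {
  dom <- data.frame(label = c("a", "b"), class = "other",
                    channel_domain = NA,
                    start = c(1L, 10L), end = c(12L, 20L),
                    divergence_a = 0.1, divergence_b = 0.1)
  expect_error(paralog_family_spec(30, dom), "overlap")
})

test_that("simulated LFP honours its zero cases and Poisson event rate", {
  # zero noise, zero events: all-zero trace
  quiet <- simulate_lfp(lfp_sim_spec(duration_s = 2, noise_amplitude = 0,
                                     seed = 1))
  expect_true(all(quiet$trace$samples == 0))
  expect_equal(nrow(quiet$events), 0)

  # response probability 1 with 10 stimuli: exactly 10 locked truth events
  stim <- seq(15, 285, by = 30)
  resp <- simulate_lfp(lfp_sim_spec(duration_s = 300, noise_amplitude = 0,
                                    stimulus_times = stim,
                                    stimulus_response_prob = 1, seed = 2))
  expect_equal(sum(resp$events$type == "stimulus"), 10)

  # 6 events/min over 10 min: mean injected count near 60
  counts <- vapply(1:50, function(s) {
    nrow(simulate_lfp(lfp_sim_spec(duration_s = 600, noise_amplitude = 0,
                                   spont_event_rate = 6, seed = s))$events)
  }, 0)
  se <- sqrt(60 / 50)
  expect_lt(abs(mean(counts) - 60), 3 * se)

  expect_error(lfp_sim_spec(duration_s = 1.2345, fs = 1000), "integer sample")
  expect_error(lfp_trace(1:10, fs = -1), "positive")
})

test_that("simulated cohorts honour burst truths and group structure", {
  sim <- simulate_cohort(cohort_sim_spec(burst_rate_a = 3, burst_rate_b = 0,
                                         seed = 4))
  expect_equal(sum(sim$truth$burst_count[sim$truth$group == "B"]), 0)
  expect_length(sim$group_a, 12)
  expect_equal(nrow(sim$group_a[[1]]$bins), 9)
  expect_true(all(sim$group_a[[1]]$bins$distance_mm >= 0))

  # burst truth equals what the burst caller recovers on the full series
  counts <- vapply(sim$group_a, count_bursts, 0)
  expect_equal(sum(counts), sum(sim$truth$burst_count[sim$truth$group == "A"]))
})

test_that("generated artifacts round-trip through the package readers", {
  fam <- simulate_paralog_family(recovery_family_spec(seed = 12))
  dir <- tempfile(); write_family(fam, dir)
  ref <- read_protein_fasta(file.path(dir, "reference.fasta"))[[1]]
  expect_identical(ref$residues, fam$reference$residues)
  doms <- read_domain_table(file.path(dir, "domains.tsv"))
  expect_equal(doms$start, fam$annotations$start)
  expect_equal(doms$label, fam$annotations$label)

  sim <- simulate_lfp(lfp_sim_spec(duration_s = 5, seed = 3,
                                   stimulus_times = c(1, 3)))
  csv <- tempfile(fileext = ".csv"); stim <- tempfile()
  write_lfp_csv(sim$trace, csv, stim)
  back <- read_lfp_csv(csv, stim)
  expect_equal(back$fs, 1000, tolerance = 1e-6)
  expect_equal(back$samples, sim$trace$samples, tolerance = 1e-6)
  expect_equal(back$stimulus_times, c(1, 3))

  coh <- simulate_cohort(cohort_sim_spec(seed = 8))
  ccsv <- tempfile(fileext = ".csv")
  write_cohort_csv(coh, ccsv)
  tracks <- read_cohort_csv(ccsv)
  expect_length(tracks, 24)
  tr <- tracks[["A01"]]
  expect_equal(tr$bins$distance_mm, coh$group_a[[1]]$bins$distance_mm,
               tolerance = 1e-6)
})
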