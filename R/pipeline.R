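#' Pipeline configuration
#'
#' Builds the configuration for the end-to-end drivers, merging user
#' settings over the assay defaults: differential-conservation flag
#' threshold 20 percentage points, burst cut-off 50 mm/s, significance
#' level 0.01, spike threshold k = 5, gap penalties 10/1, habituation trim
#' 30 min, response window 0.5 s. `read_pipeline_config()` reads the same
#' fields from a YAML file.
#'
#' @param ... named overrides of the defaults.
#' @param path YAML file.
#' @return A named list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    out_dir = ".",
    # genotype side
    ref_fasta = NULL, paralog_a_fasta = NULL, paralog_b_fasta = NULL,
    domain_table = NULL,
    gap_open = 10, gap_extend = 1,
    flag_threshold = 20,
    cds_fasta = NULL, del_start = NULL, del_len = NULL,
    # phenotype side
    lfp_csv = NULL, stimulus_file = NULL, cohort_csv = NULL,
    spike_k = 5, min_separation_ms = 100,
    window_s = 40, response_window_s = 0.5,
    burst_cutoff = 50, alpha = 0.01, trim_min = 30)
  user <- list(...)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  defaults[names(user)] <- user
  defaults
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the genotype pipeline
#'
#' Chains the sequence side of the analysis: read (or simulate) the
#' reference and two paralog proteins and the domain table, align each
#' paralog to the reference, score per-domain conservation, flag
#' differentially conserved domains, and classify the knockout edit. When
#' no sequence files are configured, the channel-like synthetic family
#' ([channel_family_spec()]) and the synthetic knockout CDS are used, and
#' the simulator truth is included in the result.
#'
#' Outputs written to `out_dir`: aligned FASTA for both paralogs,
#' `conservation.tsv`, `summary.txt`, `edit_outcome.json`.
#'
#' @param config a [pipeline_config()] list.
#' @return Invisibly, a list with the two alignments, the scored records,
#'   protein-wide identities, the edit outcome and (for simulated input)
#'   the family truth.
#' @export
run_genotype_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  scheme <- default_scoring_scheme(config$gap_open, config$gap_extend)

  truth <- NULL
  if (is.null(config$ref_fasta)) {
    truth <- simulate_paralog_family(channel_family_spec(seed = config$seed))
    ref <- truth$reference; pa <- truth$paralog_a; pb <- truth$paralog_b
    domains <- truth$annotations
  } else {
    for (f in c("ref_fasta", "paralog_a_fasta", "paralog_b_fasta",
                "domain_table"))
      if (is.null(config[[f]]) || !file.exists(config[[f]]))
        stop("missing input file for '", f, "'")
    ref <- read_protein_fasta(config$ref_fasta)[[1]]
    pa <- read_protein_fasta(config$paralog_a_fasta)[[1]]
    pb <- read_protein_fasta(config$paralog_b_fasta)[[1]]
    domains <- read_domain_table(config$domain_table,
                                 ref_length = nchar(ref$residues))
  }

  aln_a <- global_align(ref, pa, scheme)
  aln_b <- global_align(ref, pb, scheme)
  records <- score_domains(aln_a, aln_b, domains,
                           threshold = config$flag_threshold)
  id_a <- proteinwide_identity(aln_a)
  id_b <- proteinwide_identity(aln_b)

  write_alignment_fasta(aln_a, file.path(config$out_dir, "paralog_a.aln.fasta"))
  write_alignment_fasta(aln_b, file.path(config$out_dir, "paralog_b.aln.fasta"))
  summary <- write_conservation_report(
    records, file.path(config$out_dir, "conservation.tsv"),
    threshold = config$flag_threshold)
  writeLines(c(
    sprintf("protein-wide identity, paralog A vs reference: %d%% (%.2f)",
            round(id_a), id_a),
    sprintf("protein-wide identity, paralog B vs reference: %d%% (%.2f)",
            round(id_b), id_b),
    summary), file.path(config$out_dir, "summary.txt"))

  if (!is.null(config$cds_fasta)) {
    cds <- read_coding_fasta(config$cds_fasta)[[1]]
    edit <- classify_edit(cds, config$del_start, config$del_len)
  } else {
    fix <- synthetic_knockout_cds()
    edit <- classify_edit(fix$cds, fix$del_start, fix$del_len)
  }
  write_edit_outcome(edit, file.path(config$out_dir, "edit_outcome.json"))

  invisible(list(alignment_a = aln_a, alignment_b = aln_b,
                 records = records, identity_a = id_a, identity_b = id_b,
                 edit = edit, truth = truth))
}

#' Run the phenotype pipeline
#'
#' Chains the physiology/behaviour side: an LFP recording (read from CSV
#' or simulated with stimulus-locked events) is preprocessed, its 40-s
#' power spectrum computed, spikes detected and locked to the light
#' stimuli; a two-group locomotor cohort (read or simulated) is compared
#' on total activity and burst count with the exact Mann-Whitney test.
#' Simulated defaults model a burst-positive, hyperactive mutant group
#' versus wild type.
#'
#' Outputs in `out_dir`: `spectrum.tsv`, `events.tsv`, and
#' `phenotype_summary.json` holding the response fraction and both group
#' comparisons.
#'
#' @param config a [pipeline_config()] list.
#' @return Invisibly, a list with the preprocessed trace, spectrum,
#'   events, stimulus-locking result and the two comparisons.
#' @export
run_phenotype_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$lfp_csv)) {
    if (!file.exists(config$lfp_csv)) stop("missing LFP file")
    trace <- read_lfp_csv(config$lfp_csv, config$stimulus_file)
  } else {
    sim <- simulate_lfp(lfp_sim_spec(
      duration_s = 300, spont_event_rate = 2,
      stimulus_times = seq(15, 285, by = 30),
      stimulus_response_prob = 1, noise_amplitude = 1,
      mains_hum_amplitude = 0.5, seed = config$seed))
    trace <- sim$trace
  }
  pre <- preprocess(trace)
  spec40 <- power_spectrum(pre, window_s = config$window_s)
  events <- detect_spikes(pre, k = config$spike_k,
                          min_separation_ms = config$min_separation_ms)
  locking <- stimulus_locked_responses(events, pre$stimulus_times,
                                       config$response_window_s)

  if (!is.null(config$cohort_csv)) {
    if (!file.exists(config$cohort_csv)) stop("missing cohort file")
    tracks <- read_cohort_csv(config$cohort_csv)
    groups <- split(tracks, vapply(tracks, `[[`, "", "group"))
    if (length(groups) != 2) stop("cohort must hold exactly two groups")
    cohort_a <- groups[[1]]; cohort_b <- groups[[2]]
  } else {
    sim_c <- simulate_cohort(cohort_sim_spec(
      group_effect = 2, burst_rate_b = 20, seed = config$seed + 1L))
    cohort_a <- sim_c$group_a; cohort_b <- sim_c$group_b
  }
  cmp_act <- compare_groups(cohort_a, cohort_b, "activity_total",
                            trim_min = config$trim_min,
                            alpha = config$alpha)
  cmp_bur <- compare_groups(cohort_a, cohort_b, "burst_count",
                            trim_min = config$trim_min,
                            cutoff_mm_s = config$burst_cutoff,
                            alpha = config$alpha)

  write_spectrum_tsv(spec40, file.path(config$out_dir, "spectrum.tsv"))
  write_events_tsv(locking$events, file.path(config$out_dir, "events.tsv"))
  jsonlite::write_json(list(
    n_events = nrow(events),
    response_fraction = locking$response_fraction,
    activity = unclass(cmp_act$comparison),
    bursts = unclass(cmp_bur$comparison)),
    file.path(config$out_dir, "phenotype_summary.json"),
    auto_unbox = TRUE, digits = NA, na = "null")

  invisible(list(trace = pre, spectrum = spec40, events = events,
                 locking = locking, activity = cmp_act, bursts = cmp_bur))
}
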