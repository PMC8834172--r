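#' Specification of a two-group locomotor cohort
#'
#' Emulates an automated larval tracking export: per animal, distance moved
#' per time bin (90 min in 10-min bins by default, 12 animals per group)
#' plus a per-second maximum-velocity series for burst calling. Group B's
#' per-bin distance mean is multiplied by `group_effect` (1 = null).
#' Bursts are velocity excursions above the 50 mm/s cut-off, injected at a
#' Poisson number per recording; the non-burst velocity baseline stays
#' below the cut-off.
#'
#' Per-bin distances are drawn from a zero-truncated Gaussian (negative
#' draws clipped to 0) — the simplest positive-valued activity model.
#'
#' @param n_per_group animals per group (>= 2; default 12).
#' @param duration_min recording length (default 90), divisible by
#'   `bin_min`.
#' @param bin_min bin width in minutes (default 10).
#' @param baseline_distance mean distance per bin, mm.
#' @param distance_sd per-bin SD, mm.
#' @param group_effect multiplicative activity factor for group B.
#' @param burst_rate_a,burst_rate_b expected bursts per recording.
#' @param burst_velocity mm/s above the 50 mm/s cut-off at a burst second.
#' @param velocity_mean,velocity_sd baseline per-second max velocity
#'   (clipped below the cut-off).
#' @param seed integer seed.
#' @return A `cohort_sim_spec` object.
#' @export
cohort_sim_spec <- function(n_per_group = 12, duration_min = 90,
                            bin_min = 10, baseline_distance = 1200,
                            distance_sd = 300, group_effect = 1,
                            burst_rate_a = 0, burst_rate_b = 0,
                            burst_velocity = 30, velocity_mean = 20,
                            velocity_sd = 5, seed = 1L) {
  if (n_per_group < 2) stop("need at least 2 animals per group")
  if (duration_min %% bin_min != 0)
    stop("duration_min must be divisible by bin_min")
  if (min(baseline_distance, distance_sd, burst_rate_a, burst_rate_b) < 0)
    stop("rates and scales must be non-negative")
  structure(as.list(environment()), class = "cohort_sim_spec")
}

#' A single animal's locomotor track
#'
#' @param animal_id,group identifiers.
#' @param bins data.frame `bin_index`, `distance_mm`, `max_velocity_mm_s`
#'   (contiguous 1-based bin indices, non-negative distances).
#' @param bin_minutes bin width.
#' @param velocity optional fine-grained data.frame `time_s`,
#'   `velocity_mm_s` used for burst calling when present.
#' @return A `locomotor_track` object.
#' @export
locomotor_track <- function(animal_id, group, bins, bin_minutes = 10,
                            velocity = NULL) {
  stopifnot(all(c("bin_index", "distance_mm", "max_velocity_mm_s")
                %in% names(bins)))
  if (any(bins$distance_mm < 0)) stop("negative distance in track ", animal_id)
  if (nrow(bins) > 1 && any(diff(bins$bin_index) != 1L))
    stop("bin indices not contiguous in track ", animal_id)
  structure(list(animal_id = animal_id, group = group, bins = bins,
                 bin_minutes = bin_minutes, velocity = velocity),
            class = "locomotor_track")
}

#' Simulate a two-group locomotor cohort with burst ground truth
#'
#' @param spec a [cohort_sim_spec()].
#' @param cutoff_mm_s burst cut-off used for the injected excursions
#'   (default 50).
#' @return list: `group_a`, `group_b` (lists of [locomotor_track()]),
#'   `truth` data.frame (`animal_id`, `group`, `burst_count`) and the
#'   `spec`.
#' @export
simulate_cohort <- function(spec, cutoff_mm_s = 50) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  set.seed(spec$seed)
  n_bins <- spec$duration_min %/% spec$bin_min
  secs <- spec$duration_min * 60
  bin_of_sec <- rep(seq_len(n_bins), each = spec$bin_min * 60)

  sim_animal <- function(id, group, effect, burst_rate) {
    d <- pmax(0, rnorm(n_bins, spec$baseline_distance * effect,
                       spec$distance_sd))
    v <- pmin(rnorm(secs, spec$velocity_mean, spec$velocity_sd),
              cutoff_mm_s - 1)
    n_bursts <- rpois(1, burst_rate)
    if (n_bursts > 0) {
      at <- sample.int(secs, min(n_bursts, secs))
      v[at] <- cutoff_mm_s + spec$burst_velocity
      n_bursts <- length(at)
    }
    bins <- data.frame(bin_index = seq_len(n_bins), distance_mm = d,
                       max_velocity_mm_s =
                         as.numeric(tapply(v, bin_of_sec, max)))
    list(track = locomotor_track(id, group, bins, spec$bin_min,
                                 velocity = data.frame(
                                   time_s = seq_len(secs) - 1,
                                   velocity_mm_s = v)),
         burst_count = n_bursts)
  }

  ga <- lapply(seq_len(spec$n_per_group), function(i)
    sim_animal(sprintf("A%02d", i), "A", 1, spec$burst_rate_a))
  gb <- lapply(seq_len(spec$n_per_group), function(i)
    sim_animal(sprintf("B%02d", i), "B", spec$group_effect,
               spec$burst_rate_b))

  truth <- data.frame(
    animal_id = c(vapply(ga, function(x) x$track$animal_id, ""),
                  vapply(gb, function(x) x$track$animal_id, "")),
    group = rep(c("A", "B"), each = spec$n_per_group),
    burst_count = c(vapply(ga, `[[`, 0, "burst_count"),
                    vapply(gb, `[[`, 0, "burst_count")),
    stringsAsFactors = FALSE)

  list(group_a = lapply(ga, `[[`, "track"),
       group_b = lapply(gb, `[[`, "track"),
       truth = truth, spec = spec)
}

#' Write / read a cohort as CSV
#'
#' Long-format CSV `animal_id,group,bin_index,distance_mm,max_velocity_mm_s`
#' — the bin-level tracking export. The fine-grained velocity series is a
#' simulation-side extra and is not round-tripped; burst calling on a
#' re-read cohort operates at bin resolution.
#'
#' @param cohort output of [simulate_cohort()], or a list of tracks.
#' @param path CSV path.
#' @export
write_cohort_csv <- function(cohort, path) {
  tracks <- if (!is.null(cohort$group_a)) c(cohort$group_a, cohort$group_b)
            else cohort
  rows <- lapply(tracks, function(tr)
    data.frame(animal_id = tr$animal_id, group = tr$group, tr$bins,
               stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @param bin_minutes bin width of the stored tracks.
#' @return `read_cohort_csv()` returns a list of [locomotor_track()]
#'   objects split by animal.
#' @export
read_cohort_csv <- function(path, bin_minutes = 10) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "group", "bin_index", "distance_mm",
            "max_velocity_mm_s")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cohort CSV lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!nrow(df)) stop("empty cohort file: ", path)
  lapply(split(df, df$animal_id), function(d) {
    d <- d[order(d$bin_index), , drop = FALSE]
    locomotor_track(d$animal_id[1], d$group[1],
                    d[, c("bin_index", "distance_mm", "max_velocity_mm_s")],
                    bin_minutes = bin_minutes)
  })
}
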