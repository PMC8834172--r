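#' Remove the habituation period from a track
#'
#' Drops every bin (and velocity sample) starting before `trim_min`
#' minutes — animals spend the first stretch habituating to the chamber.
#' With the default 90-min recording in 10-min bins and a 30-min trim, 6
#' bins remain.
#'
#' @param track a [locomotor_track()].
#' @param trim_min minutes removed from the start (default 30).
#' @return The trimmed track (original bin indices kept).
#' @export
trim_habituation <- function(track, trim_min = 30) {
  stopifnot(inherits(track, "locomotor_track"))
  if (trim_min <= 0) return(track)
  start_min <- (track$bins$bin_index - 1) * track$bin_minutes
  keep <- start_min >= trim_min
  if (!any(keep))
    stop("trim of ", trim_min, " min leaves an empty track")
  vel <- track$velocity
  if (!is.null(vel)) vel <- vel[vel$time_s >= trim_min * 60, , drop = FALSE]
  locomotor_track(track$animal_id, track$group,
                  track$bins[keep, , drop = FALSE],
                  bin_minutes = track$bin_minutes, velocity = vel)
}

#' Total distance moved
#'
#' Sum of per-bin distances; the per-bin series is attached for plotting.
#'
#' @param track a (trimmed) [locomotor_track()].
#' @return numeric total in mm, with attribute `per_bin`.
#' @export
activity_total <- function(track) {
  stopifnot(inherits(track, "locomotor_track"))
  structure(sum(track$bins$distance_mm),
            per_bin = track$bins[, c("bin_index", "distance_mm")])
}

#' Count burst movements
#'
#' Number of contiguous supra-threshold runs of the maximum-velocity
#' series — a run of consecutive samples strictly above the cut-off counts
#' as one burst, so a single movement spanning several samples is not
#' double-counted. The fine-grained velocity series is used when the track
#' carries one; otherwise the per-bin maxima are used.
#'
#' @param track a [locomotor_track()].
#' @param cutoff_mm_s burst cut-off (default 50 mm/s).
#' @return integer burst count.
#' @export
count_bursts <- function(track, cutoff_mm_s = 50) {
  stopifnot(inherits(track, "locomotor_track"))
  series <- if (!is.null(track$velocity)) track$velocity$velocity_mm_s
            else track$bins$max_velocity_mm_s
  if (is.null(series) || !length(series) || all(is.na(series)))
    stop("no velocity data in track ", track$animal_id)
  r <- rle(series > cutoff_mm_s)
  sum(r$values)
}

#' Compare two cohorts on a locomotor metric
#'
#' Computes the chosen per-animal metric after habituation trimming, then
#' runs the (exact) Mann-Whitney U test between the groups at the assay's
#' significance level (alpha 0.01).
#'
#' @param cohort_a,cohort_b lists of [locomotor_track()] objects (>= 2
#'   animals each).
#' @param metric `"activity_total"` or `"burst_count"`.
#' @param trim_min habituation trim, minutes.
#' @param cutoff_mm_s burst cut-off for `metric = "burst_count"`.
#' @param alpha significance level (default 0.01; p <= alpha is
#'   significant).
#' @param exact_max_n exact test used when the smaller group is at most
#'   this size.
#' @return list: `comparison` (a `group_comparison`, see
#'   [mann_whitney_u()]) and `per_animal` (animal, group, metric value).
#' @export
compare_groups <- function(cohort_a, cohort_b,
                           metric = c("activity_total", "burst_count"),
                           trim_min = 30, cutoff_mm_s = 50, alpha = 0.01,
                           exact_max_n = 12) {
  metric <- match.arg(metric)
  if (length(cohort_a) < 2 || length(cohort_b) < 2)
    stop("need at least 2 animals per group")
  eval_metric <- function(track) {
    tr <- trim_habituation(track, trim_min)
    if (metric == "activity_total") as.numeric(activity_total(tr))
    else as.numeric(count_bursts(tr, cutoff_mm_s))
  }
  va <- vapply(cohort_a, eval_metric, 0)
  vb <- vapply(cohort_b, eval_metric, 0)
  per <- data.frame(
    animal_id = c(vapply(cohort_a, `[[`, "", "animal_id"),
                  vapply(cohort_b, `[[`, "", "animal_id")),
    group = c(vapply(cohort_a, `[[`, "", "group"),
              vapply(cohort_b, `[[`, "", "group")),
    value = c(va, vb), metric = metric, stringsAsFactors = FALSE)
  list(comparison = mann_whitney_u(va, vb, exact_max_n = exact_max_n,
                                   alpha = alpha),
       per_animal = per)
}
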