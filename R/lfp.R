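#' Local field potential traces
#'
#' A uniformly sampled extracellular voltage recording: sample values, the
#' sampling rate `fs` (Hz), a start time `t0` (s), optional stimulus onset
#' times, and free-form metadata (animal / genotype labels).
#'
#' @param samples numeric vector.
#' @param fs sampling rate in Hz (> 0); recordings in the assay this models
#'   are digitised at 1000 Hz.
#' @param t0 time of the first sample, seconds.
#' @param stimulus_times optional numeric vector of stimulus onsets (s),
#'   each within the trace span.
#' @param meta named list of labels.
#' @return An `lfp_trace` object.
#' @export
lfp_trace <- function(samples, fs = 1000, t0 = 0, stimulus_times = NULL,
                      meta = list()) {
  if (fs <= 0) stop("fs must be positive")
  samples <- as.numeric(samples)
  if (!length(samples)) stop("empty trace")
  span <- c(t0, t0 + length(samples) / fs)
  if (!is.null(stimulus_times)) {
    stimulus_times <- sort(as.numeric(stimulus_times))
    if (any(stimulus_times < span[1] | stimulus_times > span[2]))
      stop("stimulus times outside the trace span [",
           span[1], ", ", span[2], "] s")
  }
  structure(list(samples = samples, fs = fs, t0 = t0,
                 stimulus_times = stimulus_times, meta = meta),
            class = "lfp_trace")
}

#' @export
print.lfp_trace <- function(x, ...) {
  cat("lfp_trace: ", length(x$samples) / x$fs, " s at ", x$fs, " Hz",
      if (!is.null(x$stimulus_times))
        paste0(", ", length(x$stimulus_times), " stimuli"), "\n", sep = "")
  invisible(x)
}

#' Read / write LFP traces as CSV
#'
#' Two-column CSV `time_s,value`; the sampling rate is recovered from the
#' median time step on read. Stimulus times are newline-separated seconds
#' in a plain-text sidecar file.
#'
#' @param trace an [lfp_trace()].
#' @param path CSV path.
#' @param stimulus_path optional stimulus-time file.
#' @export
write_lfp_csv <- function(trace, path, stimulus_path = NULL) {
  t <- trace$t0 + (seq_along(trace$samples) - 1L) / trace$fs
  utils::write.csv(data.frame(time_s = t, value = trace$samples),
                   path, row.names = FALSE, quote = FALSE)
  if (!is.null(stimulus_path) && !is.null(trace$stimulus_times))
    writeLines(format(trace$stimulus_times, trim = TRUE), stimulus_path)
  invisible(path)
}

#' @rdname write_lfp_csv
#' @export
read_lfp_csv <- function(path, stimulus_path = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(df)))
    stop("expected columns time_s,value in ", path)
  dt <- median(diff(df$time_s))
  stim <- if (!is.null(stimulus_path)) as.numeric(readLines(stimulus_path))
  lfp_trace(df$value, fs = 1 / dt, t0 = df$time_s[1], stimulus_times = stim)
}

#' Specification of a synthetic LFP recording
#'
#' Baseline noise (white or 1/f) plus an optional 50 Hz mains contaminant,
#' spontaneous biphasic events at Poisson times, and stimulus-locked events
#' injected within 0.5 s after each stimulus with a set probability. The
#' event template is one positive then one negative half-sine lobe
#' (biphasic), 30 ms per lobe by default.
#'
#' @param duration_s recording length (s); `duration_s * fs` must be a
#'   whole number of samples.
#' @param fs sampling rate, default 1000 Hz.
#' @param noise_model `"white"` or `"pink"` (1/f).
#' @param noise_amplitude baseline noise SD.
#' @param spont_event_rate spontaneous events per minute.
#' @param event_amplitude peak amplitude of the event template.
#' @param event_lobe_ms width of each half-sine lobe, ms.
#' @param stimulus_times stimulus onsets (s), or `NULL`.
#' @param stimulus_response_prob probability a stimulus triggers an event.
#' @param response_window_s stimulus-locked events fall within this window
#'   after the stimulus.
#' @param mains_hum_amplitude amplitude of the 50 Hz sinusoid (0 = none).
#' @param seed integer seed.
#' @return An `lfp_sim_spec` object.
#' @export
lfp_sim_spec <- function(duration_s = 40, fs = 1000,
                         noise_model = c("white", "pink"),
                         noise_amplitude = 1,
                         spont_event_rate = 0, event_amplitude = 8,
                         event_lobe_ms = 30, stimulus_times = NULL,
                         stimulus_response_prob = 1,
                         response_window_s = 0.5,
                         mains_hum_amplitude = 0, seed = 1L) {
  if (fs <= 0) stop("fs must be positive")
  n <- duration_s * fs
  if (abs(n - round(n)) > 1e-9)
    stop("duration_s * fs must be an integer sample count")
  if (stimulus_response_prob < 0 || stimulus_response_prob > 1)
    stop("stimulus_response_prob must be in [0, 1]")
  if (!is.null(stimulus_times) &&
      any(stimulus_times < 0 | stimulus_times > duration_s))
    stop("stimulus times must lie in [0, duration_s]")
  structure(list(duration_s = duration_s, fs = fs,
                 noise_model = match.arg(noise_model),
                 noise_amplitude = noise_amplitude,
                 spont_event_rate = spont_event_rate,
                 event_amplitude = event_amplitude,
                 event_lobe_ms = event_lobe_ms,
                 stimulus_times = stimulus_times,
                 stimulus_response_prob = stimulus_response_prob,
                 response_window_s = response_window_s,
                 mains_hum_amplitude = mains_hum_amplitude,
                 seed = as.integer(seed)),
            class = "lfp_sim_spec")
}

# biphasic template: positive then negative half-sine lobe
biphasic_template <- function(fs, lobe_ms, amplitude) {
  w <- max(1L, round(fs * lobe_ms / 1000))
  lobe <- sin(pi * seq_len(w) / (w + 1))
  amplitude * c(lobe, -lobe)
}

#' Simulate an LFP recording with known event times
#'
#' @param spec an [lfp_sim_spec()].
#' @return list: `trace` (an [lfp_trace()], stimulus times attached) and
#'   `events`, a data.frame of injected event onsets with columns
#'   `onset_s`, `type` (`"spontaneous"`/`"stimulus"`) and `stimulus_index`.
#' @export
simulate_lfp <- function(spec) {
  stopifnot(inherits(spec, "lfp_sim_spec"))
  set.seed(spec$seed)
  n <- as.integer(round(spec$duration_s * spec$fs))

  x <- if (spec$noise_amplitude > 0) {
    if (spec$noise_model == "white") {
      rnorm(n, 0, spec$noise_amplitude)
    } else {
      pink_noise(n, spec$noise_amplitude)
    }
  } else numeric(n)

  if (spec$mains_hum_amplitude > 0) {
    t <- (seq_len(n) - 1L) / spec$fs
    x <- x + spec$mains_hum_amplitude * sin(2 * pi * 50 * t)
  }

  template <- biphasic_template(spec$fs, spec$event_lobe_ms,
                                spec$event_amplitude)
  tpl_s <- length(template) / spec$fs

  onsets <- numeric(0); types <- character(0); stim_idx <- integer(0)
  if (spec$spont_event_rate > 0) {
    k <- rpois(1, spec$spont_event_rate * spec$duration_s / 60)
    if (k > 0) {
      onsets <- sort(runif(k, 0, max(0, spec$duration_s - tpl_s)))
      types <- rep("spontaneous", k)
      stim_idx <- rep(NA_integer_, k)
    }
  }
  if (!is.null(spec$stimulus_times)) {
    for (i in seq_along(spec$stimulus_times)) {
      if (runif(1) <= spec$stimulus_response_prob) {
        lag <- runif(1, 0, max(1e-3, spec$response_window_s - tpl_s))
        onsets <- c(onsets, spec$stimulus_times[i] + lag)
        types <- c(types, "stimulus")
        stim_idx <- c(stim_idx, i)
      }
    }
  }

  for (o in onsets) {
    i0 <- as.integer(round(o * spec$fs)) + 1L
    idx <- i0:min(n, i0 + length(template) - 1L)
    x[idx] <- x[idx] + template[seq_along(idx)]
  }

  ord <- order(onsets)
  list(trace = lfp_trace(x, fs = spec$fs,
                         stimulus_times = spec$stimulus_times),
       events = data.frame(onset_s = onsets[ord], type = types[ord],
                           stimulus_index = stim_idx[ord],
                           stringsAsFactors = FALSE))
}

# 1/f amplitude-shaped Gaussian noise, scaled to the requested SD
pink_noise <- function(n, sd_target) {
  white <- rnorm(n)
  X <- fft(white)
  f <- c(1, seq_len(n - 1))            # avoid dividing the DC bin by zero
  f <- pmin(f, n - f + 1)              # mirror for negative frequencies
  X <- X / sqrt(f)
  x <- Re(fft(X, inverse = TRUE)) / n
  x * sd_target / sd(x)
}
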