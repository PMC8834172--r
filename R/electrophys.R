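#' Preprocess an LFP trace
#'
#' Standard LFP conditioning chain: an optional leading trim (the first
#' minute of a real recording is electrode placement), a band-stop at the
#' mains frequency (default 50 Hz, width 2 Hz) and a band-pass (default
#' 2.5-100 Hz), both applied as zero-phase spectral masks (the trace's FFT
#' is multiplied by a real 0/1 mask and inverted). Spectral masking keeps
#' event timing undistorted, removes DC and the mains line exactly, and is
#' idempotent: the mask is a projection, so filtering twice equals
#' filtering once (up to an optional raised-cosine transition band, see
#' `transition_hz`). Output length equals input length after the trim.
#'
#' @param trace an [lfp_trace()].
#' @param notch_hz mains frequency to remove; `NA` skips the notch.
#' @param notch_width_hz full stop-band width around `notch_hz`.
#' @param band two-element pass band in Hz; requires `fs > 2 * band[2]`.
#' @param transition_hz width of a raised-cosine shoulder on every band
#'   edge (0 = brick-wall mask, the default).
#' @param trim_s seconds removed from the start before filtering (default 0;
#'   use 60 for 13-minute bench recordings).
#' @return A filtered [lfp_trace()]; stimulus times are shifted by the trim.
#' @export
preprocess <- function(trace, notch_hz = 50, notch_width_hz = 2,
                       band = c(2.5, 100), transition_hz = 0, trim_s = 0) {
  stopifnot(inherits(trace, "lfp_trace"))
  fs <- trace$fs
  if (fs <= 2 * band[2])
    stop("sampling rate ", fs, " Hz too low for a ", band[2], " Hz band edge")
  x <- trace$samples
  t0 <- trace$t0
  stim <- trace$stimulus_times
  if (trim_s > 0) {
    drop <- round(trim_s * fs)
    if (drop >= length(x)) stop("trim removes the whole trace")
    x <- x[-seq_len(drop)]
    t0 <- t0 + trim_s
    if (!is.null(stim)) stim <- stim[stim >= t0]
  }
  if (length(x) < 32) stop("trace too short to filter")
  n <- length(x)
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)                 # two-sided frequency axis
  mask <- edge_mask(f, band[1], band[2], transition_hz)
  if (!is.na(notch_hz)) {
    lo <- notch_hz - notch_width_hz / 2
    hi <- notch_hz + notch_width_hz / 2
    mask <- mask * (1 - edge_mask(f, lo, hi, transition_hz))
  }
  x <- Re(fft(mask * fft(x), inverse = TRUE)) / n
  lfp_trace(x, fs = fs, t0 = t0, stimulus_times = stim, meta = trace$meta)
}

# 1 inside [lo, hi], 0 outside, raised-cosine shoulders of width w
edge_mask <- function(f, lo, hi, w) {
  m <- as.numeric(f >= lo & f <= hi)
  if (w > 0) {
    up <- f >= lo - w & f < lo
    m[up] <- 0.5 * (1 + cos(pi * (lo - f[up]) / w))
    down <- f > hi & f <= hi + w
    m[down] <- 0.5 * (1 + cos(pi * (f[down] - hi) / w))
  }
  m
}

#' One-sided power spectrum of a trace window
#'
#' Magnitude-squared FFT of one analysis window (default 40 s), linearly
#' detrended and Hann-tapered, at frequency resolution `1/window_s` Hz.
#' Power is normalised so that the one-sided sum equals the energy of the
#' detrended, tapered window (Parseval).
#'
#' @param trace an [lfp_trace()] (normally preprocessed).
#' @param window_s window length, seconds; the trace must be at least this
#'   long.
#' @param offset_s window start relative to the trace start.
#' @param detrend remove a linear trend before tapering.
#' @param taper `"hann"` or `"none"`.
#' @return A `power_spectrum`: `freqs` (0 to `fs/2`), `power`
#'   (non-negative), `window_s`, `taper`.
#' @export
power_spectrum <- function(trace, window_s = 40, offset_s = 0,
                           detrend = TRUE, taper = c("hann", "none")) {
  stopifnot(inherits(trace, "lfp_trace"))
  taper <- match.arg(taper)
  fs <- trace$fs
  n <- as.integer(round(window_s * fs))
  i0 <- as.integer(round(offset_s * fs))
  if (i0 + n > length(trace$samples))
    stop("trace too short: need ", window_s, " s from offset ", offset_s)
  x <- trace$samples[(i0 + 1L):(i0 + n)]
  if (detrend) {
    k <- seq_len(n)
    x <- x - (stats::lm.fit(cbind(1, k), x)$fitted.values)
  }
  w <- if (taper == "hann") 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
       else rep(1, n)
  xw <- x * w
  X <- fft(xw)
  p_full <- Mod(X)^2 / n
  half <- n %/% 2L
  power <- p_full[1:(half + 1L)]
  if (n %% 2L == 0L) {
    if (half > 1L) power[2:half] <- 2 * power[2:half]
  } else {
    power[2:(half + 1L)] <- 2 * power[2:(half + 1L)]
  }
  structure(list(freqs = (0:half) * fs / n, power = power,
                 window_s = window_s, taper = taper),
            class = "power_spectrum")
}

#' Integrated band power
#'
#' Sum of spectral power over `[lo, hi]` Hz (inclusive), e.g. the 2.5-20 Hz
#' low band and 40-100 Hz high band used to characterise epileptiform
#' enrichment.
#'
#' @param spectrum a `power_spectrum`.
#' @param lo,hi band edges in Hz.
#' @return numeric.
#' @export
band_power <- function(spectrum, lo, hi) {
  sel <- spectrum$freqs >= lo & spectrum$freqs <= hi
  sum(spectrum$power[sel])
}

#' Detect spike events by robust amplitude thresholding
#'
#' Marks events where the absolute signal exceeds `k` times a robust SD
#' estimate (1.4826 x the median absolute deviation of the whole trace;
#' when the MAD is zero — e.g. a near-silent baseline carrying a few large
#' events — the plain SD is used instead). Threshold crossings closer than
#' `min_separation_ms` are merged into one event. A flat trace yields an
#' empty result with a warning.
#'
#' @param trace a preprocessed [lfp_trace()].
#' @param k threshold multiplier (default 5).
#' @param min_separation_ms merge window, ms.
#' @return data.frame of class `spike_events`: `onset_s`, `peak_s`,
#'   `amplitude` (units of robust SD), `polarity` (+1/-1), sorted by onset.
#' @export
detect_spikes <- function(trace, k = 5, min_separation_ms = 100) {
  stopifnot(inherits(trace, "lfp_trace"))
  x <- trace$samples
  rsd <- stats::mad(x)            # 1.4826 * MAD by definition
  if (rsd == 0) rsd <- sd(x)
  empty <- data.frame(onset_s = numeric(0), peak_s = numeric(0),
                      amplitude = numeric(0), polarity = numeric(0))
  if (is.na(rsd) || rsd == 0) {
    warning("flat (zero-variance) trace; no events")
    return(structure(empty, class = c("spike_events", "data.frame")))
  }
  thr <- k * rsd
  above <- which(abs(x) > thr)
  if (!length(above))
    return(structure(empty, class = c("spike_events", "data.frame")))
  gap <- round(min_separation_ms / 1000 * trace$fs)
  new_event <- c(TRUE, diff(above) > gap)
  grp <- cumsum(new_event)
  onset <- tapply(above, grp, min)
  peak <- vapply(split(above, grp), function(ix) ix[which.max(abs(x[ix]))], 0)
  out <- data.frame(
    onset_s = trace$t0 + (onset - 1) / trace$fs,
    peak_s = trace$t0 + (peak - 1) / trace$fs,
    amplitude = abs(x[peak]) / rsd,
    polarity = sign(x[peak]))
  out <- out[order(out$onset_s), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("spike_events", "data.frame"))
}

#' Assign detected events to light stimuli
#'
#' Each event is assigned to the most recent stimulus when its onset falls
#' within `response_window_s` after that stimulus ("followed directly
#' after"); all other events remain spontaneous. The response fraction is
#' the proportion of stimuli with at least one locked event.
#'
#' @param events a `spike_events` data.frame (or any data.frame with
#'   `onset_s`).
#' @param stimulus_times sorted stimulus onsets, seconds.
#' @param response_window_s assignment window after each stimulus.
#' @return list: `events` (input plus `stimulus_index`, `NA` =
#'   spontaneous), `per_stimulus` (`stimulus_time`, `n_events`, `hit`) and
#'   `response_fraction` (`NA` when there are no stimuli).
#' @export
stimulus_locked_responses <- function(events, stimulus_times,
                                      response_window_s = 0.5) {
  if (is.null(stimulus_times) || !length(stimulus_times)) {
    events$stimulus_index <- rep(NA_integer_, nrow(events))
    return(list(events = events,
                per_stimulus = data.frame(stimulus_time = numeric(0),
                                          n_events = integer(0),
                                          hit = logical(0)),
                response_fraction = NA_real_))
  }
  stimulus_times <- sort(stimulus_times)
  idx <- findInterval(events$onset_s, stimulus_times)
  locked <- idx >= 1L &
    (events$onset_s - stimulus_times[pmax(idx, 1L)]) <= response_window_s
  events$stimulus_index <- ifelse(locked, idx, NA_integer_)
  n_ev <- vapply(seq_along(stimulus_times),
                 function(i) sum(events$stimulus_index == i, na.rm = TRUE), 0L)
  per <- data.frame(stimulus_time = stimulus_times, n_events = n_ev,
                    hit = n_ev > 0L)
  list(events = events, per_stimulus = per,
       response_fraction = mean(per$hit))
}

#' Write spike events / a spectrum as TSV
#'
#' @param x a `spike_events` data.frame or `power_spectrum`.
#' @param path output file.
#' @export
write_events_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
write_spectrum_tsv <- function(x, path) {
  utils::write.table(data.frame(freq_hz = x$freqs, power = x$power),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
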