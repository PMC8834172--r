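make_sine <- function(freq, duration_s = 40, fs = 1000, amp = 1) {
  t <- (seq_len(duration_s * fs) - 1) / fs
  lfp_trace(amp * sin(2 * pi * freq * t), fs = fs)
}
rms <- function(x) sqrt(mean(x^2))

test_that("the notch removes 50 Hz and the band-pass spares 10 Hz", {
  hum <- make_sine(50)
  out <- preprocess(hum)
  expect_lt(rms(out$samples), 0.05 * rms(hum$samples))

  tone <- make_sine(10)
  kept <- preprocess(tone)
  expect_lt(abs(rms(kept$samples) - rms(tone$samples)) / rms(tone$samples),
            0.05)

  dc <- lfp_trace(rep(3, 4000), fs = 1000)
  expect_lt(rms(preprocess(dc)$samples), 0.02 * 3)

  expect_error(preprocess(lfp_trace(rnorm(1000), fs = 150)), "too low")
})

test_that("preprocessing is idempotent up to filter tolerance", {
  set.seed(14)
  tr <- lfp_trace(rnorm(20000), fs = 1000)
  once <- preprocess(tr)
  twice <- preprocess(once)
  expect_lt(abs(rms(twice$samples) - rms(once$samples)) / rms(once$samples),
            0.01)
})

test_that("spectra peak at the tone frequency and satisfy Parseval", {
  sp <- power_spectrum(make_sine(10), window_s = 40)
  expect_equal(sp$freqs[which.max(sp$power)], 10)
  expect_equal(sp$freqs[1], 0)
  expect_equal(sp$freqs[length(sp$freqs)], 500)
  expect_equal(diff(sp$freqs[1:2]), 1 / 40)
  expect_true(all(sp$power >= 0))

  # Parseval on an untapered, undetrended window: one-sided power sums to
  # the window energy
  set.seed(3)
  x <- rnorm(40000)
  sp2 <- power_spectrum(lfp_trace(x, fs = 1000), window_s = 40,
                        detrend = FALSE, taper = "none")
  expect_lt(abs(sum(sp2$power) - sum(x^2)) / sum(x^2), 1e-6)

  expect_error(power_spectrum(lfp_trace(rnorm(100), fs = 1000), 40),
               "too short")
})

test_that("injected events enrich both low and high frequency bands", {
  stim_free <- lfp_sim_spec(duration_s = 40, noise_amplitude = 1,
                            spont_event_rate = 0, seed = 17)
  with_ev <- lfp_sim_spec(duration_s = 40, noise_amplitude = 1,
                          spont_event_rate = 15, seed = 17)
  base <- power_spectrum(preprocess(simulate_lfp(stim_free)$trace))
  ev <- power_spectrum(preprocess(simulate_lfp(with_ev)$trace))
  expect_gt(band_power(ev, 2.5, 20), band_power(base, 2.5, 20))
  expect_gt(band_power(ev, 40, 100), band_power(base, 40, 100))
})

test_that("spike detection recovers injected events and stays quiet on noise", {
  # three large events on a whisper of noise: detect all three near truth
  spec <- lfp_sim_spec(duration_s = 30, noise_amplitude = 0.05,
                       spont_event_rate = 6, seed = 8)
  sim <- simulate_lfp(spec)
  n_truth <- nrow(sim$events)
  ev <- detect_spikes(sim$trace, k = 5)
  expect_equal(nrow(ev), n_truth)
  expect_true(all(abs(ev$onset_s - sim$events$onset_s) <= 0.010))

  # flat trace: empty result with a warning
  flat <- lfp_trace(rep(0, 5000), fs = 1000)
  expect_warning(out <- detect_spikes(flat), "flat")
  expect_equal(nrow(out), 0)

  # pure noise at k = 8: essentially no false positives in 5 minutes
  noise <- simulate_lfp(lfp_sim_spec(duration_s = 300, noise_amplitude = 1,
                                     seed = 9))$trace
  expect_lte(nrow(detect_spikes(preprocess(noise), k = 8)), 1)
})

test_that("detector sensitivity is monotone non-increasing in k", {
  sim <- simulate_lfp(lfp_sim_spec(duration_s = 60, noise_amplitude = 1,
                                   spont_event_rate = 10, event_amplitude = 6,
                                   seed = 11))
  pre <- preprocess(sim$trace)
  counts <- vapply(c(3, 5, 7, 9), function(k) nrow(detect_spikes(pre, k)), 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("events lock to the most recent stimulus within the window", {
  stim <- c(10, 40, 70)
  ev <- data.frame(onset_s = c(10.2, 40.6, 69.9, 70.3))
  res <- stimulus_locked_responses(ev, stim, response_window_s = 0.5)
  expect_equal(res$events$stimulus_index, c(1L, NA, NA, 3L))
  expect_equal(res$per_stimulus$hit, c(TRUE, FALSE, TRUE))
  expect_equal(res$response_fraction, 2 / 3)

  # events strictly between windows: fraction 0
  none <- stimulus_locked_responses(data.frame(onset_s = c(20, 55)), stim)
  expect_equal(none$response_fraction, 0)

  # no stimuli: all spontaneous, fraction undefined
  free <- stimulus_locked_responses(ev, numeric(0))
  expect_true(all(is.na(free$events$stimulus_index)))
  expect_true(is.na(free$response_fraction))
})

test_that("perfect simulated responses give a response fraction of 1", {
  stim <- seq(15, 285, by = 30)    # 10 stimuli at 30 s intervals over 5 min
  sim <- simulate_lfp(lfp_sim_spec(duration_s = 300, noise_amplitude = 0.05,
                                   stimulus_times = stim,
                                   stimulus_response_prob = 1, seed = 6))
  ev <- detect_spikes(sim$trace, k = 5)
  res <- stimulus_locked_responses(ev, stim)
  expect_equal(res$response_fraction, 1)
})
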