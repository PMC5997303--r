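test_that("flat and subthreshold traces yield no detections", {
  sw <- make_cc_sweep(function(t) rep(-66, length(t)))
  expect_equal(nrow(detect_spikes(sw)), 0)
  expect_error(detect_spikes(fs_sweep(rep(0, 100), mode = "voltage_clamp")),
               "current-clamp")
})

test_that("detected spikes match the simulator log on noiseless traces", {
  p <- fs_preset_quiet()
  rec <- simulate_current_clamp(p, step_protocol(seq(-100, 700, by = 100)),
                                seed = 21)
  log <- spike_log(rec)
  for (k in seq_along(rec$sweeps)) {
    det <- detect_spikes(rec$sweeps[[k]])
    expect_equal(det$peak_t, log[[k]])
  }
})

test_that("detections closer than 1 ms collapse onto the earlier spike", {
  t <- seq(0, 99.9, by = dt_ms)
  v <- -66 + triangular_spike(t, 50, -66, 20, 0.3) +
    triangular_spike(t, 50.8, -66, 20, 0.3)
  sw <- fs_sweep(v, stimulus_onset = 10, stimulus_duration = 80,
                 stimulus_amplitude = 100)
  det <- detect_spikes(sw)
  expect_equal(nrow(det), 1)
  expect_equal(det$peak_t, 50)
})

test_that("threshold sits where dV/dt first reaches 20 V/s", {
  # ramp of exactly 25 V/s (= 2.5 mV/ms... 25 mV/ms) after a flat segment
  t <- seq(0, 99.9, by = dt_ms)
  t0 <- 50
  v <- ifelse(t < t0, -66, pmin(-66 + 25 * (t - t0), 20))
  v[t > t0 + 4] <- -70                        # crude fall so a peak exists
  sw <- fs_sweep(v, stimulus_onset = 10, stimulus_duration = 80,
                 stimulus_amplitude = 100)
  pk <- detect_spikes(sw)
  thr <- ap_threshold(sw, pk$peak_t[1])
  expect_lte(abs(thr$threshold_t - t0), dt_ms + 1e-9)
  # brute-force oracle: first sample before the peak whose central
  # difference reaches 20 V/s (derivative is monotone here)
  d <- c(0, diff(v, lag = 2) / (2 * dt_ms), 0)
  ip <- round(pk$peak_t[1] / dt_ms) + 1
  k <- which(d[1:(ip - 1)] >= 20)[1]
  expect_equal(thr$threshold_t, (k - 1) * dt_ms)
  expect_equal(thr$threshold_v, v[k])
})

test_that("sub-threshold-slope bumps raise a measurement error", {
  # local maximum reached with dV/dt ~ 5 V/s only
  t <- seq(0, 99.9, by = dt_ms)
  v <- -66 + gaussian_spike(t, 50, 4, 3)
  sw <- fs_sweep(v, stimulus_onset = 10, stimulus_duration = 80)
  expect_error(ap_threshold(sw, 50), "never reaches")
})

test_that("amplitude is peak minus threshold", {
  expect_equal(ap_amplitude(23, -40.4), 63.4)
  expect_equal(ap_amplitude(-40, -40), 0)
})

test_that("half-width is the half-level crossing interval", {
  t <- seq(0, 99.9, by = dt_ms)
  # symmetric triangle: 40 mV above a -60 baseline, half level at -40;
  # half-base 1 ms -> the -40 level is crossed 0.5 ms either side of peak
  v <- -60 + triangular_spike(t, 50, -60, -20, 1)
  sw <- fs_sweep(v, stimulus_onset = 10, stimulus_duration = 80)
  expect_equal(ap_half_width(sw, 50, threshold_v = -60), 1, tolerance = 1e-6)
})

test_that("half-width of a Gaussian spike equals the analytic FWHM", {
  t <- seq(0, 99.9, by = dt_ms)
  for (sd_ms in c(0.2, 0.5, 1)) {
    v <- -60 + gaussian_spike(t, 50.05, 50, sd_ms)
    sw <- fs_sweep(v, stimulus_onset = 10, stimulus_duration = 80)
    hw <- ap_half_width(sw, t[which.max(v)], threshold_v = -60)
    expect_equal(hw, 2 * sqrt(2 * log(2)) * sd_ms, tolerance = dt_ms)
  }
})

test_that("half-width halves when the waveform is time-compressed", {
  t <- seq(0, 99.9, by = dt_ms)
  v1 <- -60 + gaussian_spike(t, 50, 50, 0.6)
  v2 <- -60 + gaussian_spike(t, 50, 50, 0.3)
  hw1 <- ap_half_width(fs_sweep(v1, stimulus_onset = 10,
                                stimulus_duration = 80), 50, -60)
  hw2 <- ap_half_width(fs_sweep(v2, stimulus_onset = 10,
                                stimulus_duration = 80), 50, -60)
  expect_equal(hw1 / 2, hw2, tolerance = dt_ms)
})

test_that("a truncated spike raises a measurement error", {
  t <- seq(0, 99.9, by = dt_ms)
  v <- ifelse(t < 95, -60, -60 + (t - 95) * 8)   # rises off the end
  v[t > 99] <- max(v) - 0.001 * (t[t > 99] - 99) # barely-falling tail
  sw <- fs_sweep(v, stimulus_onset = 10, stimulus_duration = 80)
  pk <- which.max(v)
  expect_error(ap_half_width(sw, (pk - 1) * dt_ms, threshold_v = -60),
               "truncated")
})

test_that("latency is peak time minus stimulus onset", {
  expect_equal(ap_latency(149.5, 100), 49.5)
  expect_error(ap_latency(90, 100), "precedes")
})

test_that("fAHP measures the post-spike trough relative to threshold", {
  t <- seq(0, 99.9, by = dt_ms)
  v <- -60 + triangular_spike(t, 50, -60, 0, 0.5)
  v[t > 50.5 & t <= 52.5] <- -62 - 10 * exp(-(t[t > 50.5 & t <= 52.5] - 52))
  trough_t <- t[which.min(v)]
  sw <- fs_sweep(v, stimulus_onset = 10, stimulus_duration = 80)
  res <- fahp(sw, 50, threshold_v = -40, threshold_t = 49.5)
  expect_false(res$flagged)
  expect_equal(res$amplitude, -40 - min(v))
  expect_equal(res$latency, trough_t - 49.5)
  # monotonic decay with no undershoot below threshold -> flagged zero
  v2 <- -30 - 0.1 * t
  sw2 <- fs_sweep(v2, stimulus_onset = 10, stimulus_duration = 80)
  res2 <- fahp(sw2, 5, threshold_v = -40, threshold_t = 4.5)
  expect_true(res2$flagged)
  expect_equal(res2$amplitude, 0)
})

test_that("simulated spikes reproduce the model's reset in the fAHP", {
  p <- fs_preset_quiet()
  rec <- simulate_current_clamp(p, first_ap_protocol(), seed = 13)
  f <- first_ap_features(rec)
  expect_false(is.null(f))
  expect_equal(f$fahp_amplitude, f$threshold_v - (-55), tolerance = 1)
  expect_equal(f$peak_v, 0)                  # v_peak preset
  expect_lt(f$half_width, 1)
  expect_gt(f$latency, 0)
})

test_that("voltage-relative features are time-shift invariant and
           time features are offset invariant", {
  t <- seq(0, 99.9, by = dt_ms)
  mk <- function(shift_ms, offset_mv) {
    v <- -60 + offset_mv + triangular_spike(t, 50 + shift_ms,
                                            -60 + offset_mv, offset_mv, 0.6)
    fs_sweep(v, stimulus_onset = 10, stimulus_duration = 80,
             stimulus_amplitude = 80)
  }
  base <- mk(0, 0)
  shifted <- mk(7.7, 0)
  offset <- mk(0, 5)
  m0 <- measure_spike(base, detect_spikes(base)$peak_t[1])
  ms <- measure_spike(shifted, detect_spikes(shifted)$peak_t[1])
  mo <- measure_spike(offset, detect_spikes(offset)$peak_t[1])
  expect_equal(ms$amplitude, m0$amplitude)
  expect_equal(ms$half_width, m0$half_width)
  expect_equal(ms$fahp_amplitude, m0$fahp_amplitude)
  expect_equal(mo$half_width, m0$half_width, tolerance = 1e-9)
  expect_equal(mo$threshold_t, m0$threshold_t)
  expect_equal(mo$peak_t, m0$peak_t)
  expect_equal(mo$amplitude, m0$amplitude, tolerance = 1e-9)
})

test_that("broadening follows (HW2-HW1)/HW1 and is null in the simulator", {
  expect_equal((0.53 - 0.50) / 0.50, 0.06)   # formula anchor
  p <- fs_preset_quiet(a = 0, b = 0)          # no adaptation: null model
  rec <- simulate_current_clamp(p, step_protocol(seq(-100, 700, by = 20)),
                                seed = 17)
  expect_lt(abs(ap_broadening(rec)), 0.02)
})

test_that("max firing frequency is spikes over the 500 ms window", {
  p <- fs_preset_quiet()
  rec <- simulate_current_clamp(p, step_protocol(seq(100, 500, by = 100)),
                                seed = 19)
  counts <- lengths(spike_log(rec))
  expect_equal(max_firing_frequency(rec), max(counts) * 2)
  silent <- simulate_current_clamp(p, step_protocol(c(-100, -50)), seed = 1)
  expect_true(is.na(max_firing_frequency(silent)))
})

test_that("if_curve aggregates per-current rates across cells", {
  mk_cell <- function(rates) {
    # one synthetic sweep per current, containing `rate/2` triangular spikes
    sweeps <- lapply(seq_along(rates), function(i) {
      t <- seq(0, 649.9, by = dt_ms)
      v <- rep(-66, length(t))
      n_sp <- rates[i] / 2
      if (n_sp > 0) {
        for (pt in seq(110, 590, length.out = n_sp)) {
          v <- v + triangular_spike(t, round(pt, 1), -66, 10, 0.4)
        }
      }
      fs_sweep(v, stimulus_onset = 100, stimulus_duration = 500,
               stimulus_amplitude = 100 * i, mode = "current_clamp")
    })
    fs_recording(sweeps)
  }
  one <- if_curve(mk_cell(c(50, 100)))
  expect_equal(one$mean_rate, c(50, 100))
  two <- if_curve(list(mk_cell(c(100, 100)), mk_cell(c(100, 200))))
  expect_equal(two$mean_rate, c(100, 150))
  expect_equal(two$sd_rate[2], sd(c(100, 200)))
  expect_equal(two$sd_rate[2], 70.71, tolerance = 1e-3)
  expect_equal(two$n, c(2, 2))
  expect_error(if_curve(list()), "fs_recording")
})

test_that("population I-f mean tracks the single-cell curve under noise", {
  p <- neuron_params()                        # noise on
  proto <- step_protocol(seq(100, 600, by = 250))
  recs <- lapply(1:6, function(i) simulate_current_clamp(p, proto, seed = i))
  pop <- if_curve(recs)
  ref <- if_curve(simulate_current_clamp(fs_preset_quiet(), proto,
                                         seed = 100))
  expect_true(all(abs(pop$mean_rate - ref$mean_rate) <=
                    pmax(0.1 * ref$mean_rate, 4)))
})

test_that("accommodation metrics compare last and first 100 ms", {
  t <- seq(0, 649.9, by = dt_ms)
  regular <- rep(-66, length(t))
  for (pt in seq(105, 595, by = 35)) {
    regular <- regular + triangular_spike(t, pt, -66, 10, 0.4)
  }
  sw <- fs_sweep(regular, stimulus_onset = 100, stimulus_duration = 500,
                 stimulus_amplitude = 500)
  m <- accommodation_metrics(sw)
  expect_equal(m$adaptation_ratio, 1)
  expect_equal(m$amplitude_attenuation, 0, tolerance = 1e-6)
  # halved late rate
  slowed <- rep(-66, length(t))
  # 8 spikes in the first 100 ms, 4 in the last 100 ms -> ratio 0.5
  for (pt in c(seq(105, 189, by = 12), seq(210, 490, by = 25),
               seq(505, 595, by = 30))) {
    slowed <- slowed + triangular_spike(t, pt, -66, 10, 0.4)
  }
  sw2 <- fs_sweep(slowed, stimulus_onset = 100, stimulus_duration = 500,
                  stimulus_amplitude = 500)
  m2 <- accommodation_metrics(sw2)
  expect_equal(m2$adaptation_ratio, 0.5, tolerance = 1e-9)
  # too few spikes -> not applicable
  sparse <- fs_sweep(-66 + triangular_spike(t, 300, -66, 10, 0.4),
                     stimulus_onset = 100, stimulus_duration = 500)
  expect_true(is.na(accommodation_metrics(sparse)$adaptation_ratio))
})

test_that("spike-triggered adaptation slows the late train", {
  pb <- fs_preset_quiet(b = 60, tau_w = 120)
  recb <- simulate_current_clamp(pb, step_protocol(c(500)), seed = 1)
  m <- accommodation_metrics(recb$sweeps[[1]])
  expect_lt(m$adaptation_ratio, 1)
})
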