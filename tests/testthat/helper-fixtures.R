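# Synthetic trace builders used across the test files. All traces are built
# on the 10 kHz grid (dt = 0.1 ms) the package assumes by default.

dt_ms <- 0.1

# Current-clamp step sweep from an explicit voltage function of time (ms).
make_cc_sweep <- function(f, total = 650, onset = 100, duration = 500,
                          amplitude = -100) {
  t <- seq(0, total - dt_ms, by = dt_ms)
  fs_sweep(f(t), sampling_rate = 10000, stimulus_onset = onset,
           stimulus_duration = duration, stimulus_amplitude = amplitude,
           mode = "current_clamp")
}

# Ideal RC response to a step: baseline v0, exponential to v0 + dv.
rc_response <- function(v0, dv, tau, onset = 100, duration = 500) {
  function(t) {
    out <- rep(v0, length(t))
    during <- t > onset & t <= onset + duration
    out[during] <- v0 + dv * (1 - exp(-(t[during] - onset) / tau))
    after <- t > onset + duration
    v_end <- v0 + dv * (1 - exp(-duration / tau))
    out[after] <- v0 + (v_end - v0) * exp(-(t[after] - onset - duration) / tau)
    out
  }
}

# Flat-step recording with given steady deflections (ideal Ohmic cell).
ohmic_recording <- function(amps, r_mohm, v0 = -66) {
  sweeps <- lapply(amps, function(a) {
    dv <- a * r_mohm / 1000          # pA * MOhm -> mV
    make_cc_sweep(function(t) ifelse(t > 100 & t <= 600, v0 + dv, v0),
                  amplitude = a)
  })
  fs_recording(sweeps)
}

# Insert a triangular spike (linear rise/fall) into a baseline trace.
# peak_t/base_v/peak_v in ms/mV; rise and fall take `half_base` ms each.
triangular_spike <- function(t, peak_t, base_v, peak_v, half_base) {
  v <- numeric(length(t))
  up <- t >= peak_t - half_base & t <= peak_t
  dn <- t > peak_t & t <= peak_t + half_base
  v[up] <- (peak_v - base_v) * (1 - (peak_t - t[up]) / half_base)
  v[dn] <- (peak_v - base_v) * (1 - (t[dn] - peak_t) / half_base)
  v
}

# Gaussian-shaped spike bump (returns the bump, add to a baseline).
gaussian_spike <- function(t, peak_t, height, sd_ms) {
  height * exp(-(t - peak_t)^2 / (2 * sd_ms^2))
}

# Random small recording for round-trip property tests.
random_recording <- function(n_sweeps = 3, n_samples = 200) {
  sweeps <- lapply(seq_len(n_sweeps), function(j) {
    fs_sweep(stats::rnorm(n_samples, -60, 5), sampling_rate = 10000,
             stimulus_onset = 5, stimulus_duration = 10,
             stimulus_amplitude = 10 * j,
             mode = "current_clamp")
  })
  fs_recording(sweeps, cell_id = sprintf("rand%03d", sample.int(999, 1)),
               annotations = list(note = "round-trip fixture"))
}

# Fast-spiking presets used in several files (noise off unless stated).
fs_preset_quiet <- function(...) neuron_params(noise_sd = 0, ...)
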