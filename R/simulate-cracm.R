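#' Parameters for the light-evoked EPSC sweep generator
#'
#' Describes voltage-clamp sweeps in which a brief (1 ms) light pulse evokes
#' an inward glutamatergic current in a cell held at -70 mV. Pulses are
#' delivered at 0.1 Hz, so consecutive sweeps are treated as independent
#' trials. Defaults follow the study conditions: a ~69 pA connected-cell
#' response, a residual fraction of 2.5/69 under glutamate-receptor
#' antagonists, and ten consecutive sweeps per condition.
#'
#' @param true_amplitude Peak EPSC amplitude, pA (positive magnitude of the
#'   inward current).
#' @param rise_tau,decay_tau Rise and decay time constants of the synaptic
#'   waveform, ms (`rise_tau < decay_tau`).
#' @param onset_latency Mean synaptic onset latency after the light pulse, ms.
#' @param latency_jitter_sd Sweep-to-sweep latency jitter, ms.
#' @param failure_prob Probability that a trial releases nothing.
#' @param noise_sd White current noise per sample, pA.
#' @param n_sweeps Number of sweeps per condition.
#' @param light_period Inter-pulse period, s (default 10 = 0.1 Hz; recorded
#'   as metadata).
#' @param block_fraction Residual amplitude fraction under antagonists.
#' @return An object of class `fs_epsc_sim_params`.
#' @export
epsc_sim_params <- function(true_amplitude = 69, rise_tau = 0.5,
                            decay_tau = 5, onset_latency = 3,
                            latency_jitter_sd = 0.3, failure_prob = 0,
                            noise_sd = 4, n_sweeps = 10, light_period = 10,
                            block_fraction = 2.5 / 69) {
  if (rise_tau >= decay_tau) stop("rise_tau must be < decay_tau", call. = FALSE)
  if (failure_prob < 0 || failure_prob > 1) {
    stop("failure_prob must be in [0, 1]", call. = FALSE)
  }
  if (block_fraction < 0 || block_fraction > 1) {
    stop("block_fraction must be in [0, 1]", call. = FALSE)
  }
  if (true_amplitude < 0 || noise_sd < 0 || n_sweeps < 1) {
    stop("invalid EPSC simulation parameters", call. = FALSE)
  }
  structure(list(true_amplitude = true_amplitude, rise_tau = rise_tau,
                 decay_tau = decay_tau, onset_latency = onset_latency,
                 latency_jitter_sd = latency_jitter_sd,
                 failure_prob = failure_prob, noise_sd = noise_sd,
                 n_sweeps = as.integer(n_sweeps),
                 light_period = light_period,
                 block_fraction = block_fraction),
            class = "fs_epsc_sim_params")
}

#' Simulate light-pulse-aligned voltage-clamp sweeps
#'
#' Generates a control recording and a pharmacologically blocked recording
#' for one cell. Each sweep holds 100 ms of baseline, a 1 ms light marker,
#' and 100 ms of post-light trace containing (unless the trial fails) a
#' difference-of-exponentials inward synaptic current. The blocked recording
#' scales the synaptic amplitude by `block_fraction`, emulating bath-applied
#' AMPA/NMDA receptor antagonists; trial-level failures and latency jitter
#' are redrawn independently per condition.
#'
#' @param params An [epsc_sim_params()] object.
#' @param seed Integer seed; output is bit-reproducible given
#'   `(params, seed)`.
#' @param cell_id Cell identifier.
#' @return List with `control` and `blocked`, both [fs_recording()]s in
#'   voltage-clamp mode (pA; inward currents negative).
#' @export
simulate_cracm_sweeps <- function(params, seed = 1, cell_id = "sim") {
  stopifnot(inherits(params, "fs_epsc_sim_params"))
  fs <- 10000
  dt <- 1000 / fs
  light_on <- 100                 # ms
  n <- round(200 / dt)            # 200 ms sweeps
  t <- (seq_len(n) - 1) * dt
  make_rec <- function(amplitude) {
    sweeps <- lapply(seq_len(params$n_sweeps), function(j) {
      i <- numeric(n)
      if (params$noise_sd > 0) i <- stats::rnorm(n, 0, params$noise_sd)
      fail <- stats::runif(1) < params$failure_prob
      lat <- params$onset_latency +
        stats::rnorm(1, 0, params$latency_jitter_sd)
      if (!fail && amplitude > 0) {
        t0 <- light_on + max(lat, 0)
        tr <- t - t0
        w <- ifelse(tr > 0,
                    exp(-tr / params$decay_tau) - exp(-tr / params$rise_tau),
                    0)
        pk <- max(w)
        if (pk > 0) i <- i - amplitude * w / pk   # inward = negative
      }
      fs_sweep(i, sampling_rate = fs, stimulus_onset = light_on,
               stimulus_duration = 1, stimulus_amplitude = 1,
               mode = "voltage_clamp")
    })
    fs_recording(sweeps, cell_id = cell_id,
                 annotations = list(light_period_s = params$light_period,
                                    holding_mv = -70))
  }
  with_local_seed(seed, {
    control <- make_rec(params$true_amplitude)
    blocked <- make_rec(params$true_amplitude * params$block_fraction)
    list(control = control, blocked = blocked)
  })
}
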