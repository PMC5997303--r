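#' Model-neuron parameters for the current-clamp simulator
#'
#' Parameters of an adaptive exponential integrate-and-fire neuron augmented
#' with a first-order H-current, the generative model behind
#' [simulate_current_clamp()]. The default preset is a fast-spiking cell:
#' small capacitance, high leak (hence short time constant), a steep spike
#' initiation (`delta_t` = 1 mV), weak spike-triggered adaptation (so trains
#' show little accommodation), and a small H-conductance producing a
#' hyperpolarization sag ratio near 0.96 on a -100 pA step.
#'
#' @param c_m Membrane capacitance, pF.
#' @param g_l Leak conductance, nS. Input resistance of the passive model is
#'   `1/g_l` (GOhm), membrane time constant `c_m/g_l` (ms).
#' @param e_l Leak reversal, mV.
#' @param v_t Spike-initiation threshold parameter, mV.
#' @param delta_t Slope factor of the exponential spike term, mV.
#' @param a Subthreshold adaptation conductance, nS.
#' @param b Spike-triggered adaptation increment, pA.
#' @param tau_w Adaptation time constant, ms.
#' @param v_reset Post-spike reset potential, mV.
#' @param v_peak Spike cutoff, mV; the emitted sample at a spike.
#' @param g_h H-type (sag) conductance, nS; 0 disables the sag mechanism.
#' @param e_h H-current reversal, mV.
#' @param tau_h H-current activation time constant, ms.
#' @param refractory Absolute refractory period, ms; the membrane is clamped
#'   at `v_reset` for this long after each spike.
#' @param noise_sd Per-sample white current noise, pA.
#' @return An object of class `fs_neuron_params`.
#' @export
neuron_params <- function(c_m = 40, g_l = 3, e_l = -66, v_t = -42,
                          delta_t = 1, a = 0, b = 5, tau_w = 30,
                          v_reset = -55, v_peak = 0, g_h = 0.25, e_h = -30,
                          tau_h = 50, refractory = 1, noise_sd = 5) {
  p <- list(c_m = c_m, g_l = g_l, e_l = e_l, v_t = v_t, delta_t = delta_t,
            a = a, b = b, tau_w = tau_w, v_reset = v_reset, v_peak = v_peak,
            g_h = g_h, e_h = e_h, tau_h = tau_h, refractory = refractory,
            noise_sd = noise_sd)
  if (any(vapply(p, length, 0L) != 1L) || !all(vapply(p, is.numeric, TRUE))) {
    stop("all neuron parameters must be single numbers", call. = FALSE)
  }
  if (c_m <= 0 || g_l <= 0 || tau_w <= 0 || tau_h <= 0 || delta_t <= 0) {
    stop("c_m, g_l, tau_w, tau_h and delta_t must be positive", call. = FALSE)
  }
  if (g_h < 0) stop("g_h must be >= 0", call. = FALSE)
  if (v_reset >= v_peak) stop("v_reset must be below v_peak", call. = FALSE)
  if (refractory < 0 || noise_sd < 0) {
    stop("refractory and noise_sd must be >= 0", call. = FALSE)
  }
  structure(p, class = "fs_neuron_params")
}

#' @export
print.fs_neuron_params <- function(x, ...) {
  cat(sprintf(
    paste0("<fs_neuron_params> C=%g pF, g_L=%g nS (R=%.1f MOhm, tau=%.2f ms), ",
           "E_L=%g mV, V_T=%g mV, Delta_T=%g mV\n  adaptation a=%g nS, ",
           "b=%g pA, tau_w=%g ms; reset %g mV, peak %g mV; H: g_h=%g nS, ",
           "E_h=%g mV, tau_h=%g ms; refractory %g ms; noise %g pA\n"),
    x$c_m, x$g_l, 1000 / x$g_l, x$c_m / x$g_l, x$e_l, x$v_t, x$delta_t,
    x$a, x$b, x$tau_w, x$v_reset, x$v_peak, x$g_h, x$e_h, x$tau_h,
    x$refractory, x$noise_sd))
  invisible(x)
}

#' Current-step protocol description
#'
#' @param step_amplitudes Strictly increasing vector of step amplitudes, pA.
#'   Default: -100 to 1500 pA in 50 pA increments, the full
#'   characterization protocol.
#' @param step_duration Step duration, ms (default 500).
#' @param baseline Pre-stimulus holding segment, ms (default 100).
#' @param tail Post-stimulus segment, ms (default 50).
#' @return An object of class `fs_step_protocol`.
#' @export
step_protocol <- function(step_amplitudes = seq(-100, 1500, by = 50),
                          step_duration = 500, baseline = 100, tail = 50) {
  step_amplitudes <- as.numeric(step_amplitudes)
  if (length(step_amplitudes) == 0 || any(diff(step_amplitudes) <= 0)) {
    stop("step_amplitudes must be a non-empty strictly increasing vector",
         call. = FALSE)
  }
  if (step_duration <= 0 || baseline < 0 || tail < 0) {
    stop("invalid protocol timing", call. = FALSE)
  }
  structure(list(step_amplitudes = step_amplitudes,
                 step_duration = step_duration,
                 baseline = baseline, tail = tail),
            class = "fs_step_protocol")
}

#' First-AP protocol: 20-100 pA in 20 pA increments
#'
#' The small-step series used to evoke the first action potential, from which
#' single-AP features (threshold, amplitude, half-width, latency, fAHP) are
#' measured.
#'
#' @inheritParams step_protocol
#' @return An `fs_step_protocol`.
#' @export
first_ap_protocol <- function(step_duration = 500, baseline = 100,
                              tail = 50) {
  step_protocol(seq(20, 100, by = 20), step_duration, baseline, tail)
}

#' Simulate a current-clamp step recording
#'
#' Integrates an adaptive exponential integrate-and-fire membrane with a
#' first-order H-current by forward Euler at the sampling interval, one sweep
#' per step amplitude. The fixed-step integrator is deliberate: simulated
#' traces land exactly on the sample grid the extractors operate on.
#'
#' Dynamics (V in mV, currents in pA, conductances in nS, time in ms):
#' \deqn{C dV/dt = -g_L (V - E_L) + g_L \Delta_T e^{(V - V_T)/\Delta_T}
#'   - w - g_h h (V - E_h) + I(t)}
#' \deqn{\tau_w dw/dt = a (V - E_L) - w, \qquad
#'   \tau_h dh/dt = h_\infty(V) - h}
#' with \eqn{h_\infty(V) = 1 / (1 + e^{(V + 80)/8})} (activated by
#' hyperpolarization). Once V passes the spike-initiation point
#' `v_t + 3 delta_t` the exponential term diverges within a fraction of a
#' sample, so the transient itself is emitted as a stereotyped sample-aligned
#' waveform rising to `v_peak` (the logged spike sample) and repolarizing to
#' `v_reset`, where the membrane is held for the refractory period and `w`
#' increments by `b`. Every simulated spike therefore has an identical,
#' well-defined shape on the sample grid — deliberate, since these traces are
#' ground truth for waveform extractors (amplitude, half-width, fAHP).
#'
#' The per-sweep spike times logged by the integrator are available via
#' [spike_log()] and serve as the ground-truth oracle for the spike detector.
#'
#' @param params An [neuron_params()] object.
#' @param protocol An [step_protocol()] object.
#' @param seed Integer seed; output is bit-reproducible given
#'   `(params, protocol, seed)`.
#' @param cell_id Cell identifier stored in the recording.
#' @return An [fs_recording()] (current clamp, mV) with one sweep per step.
#' @export
simulate_current_clamp <- function(params, protocol, seed = 1,
                                   cell_id = "sim") {
  stopifnot(inherits(params, "fs_neuron_params"),
            inherits(protocol, "fs_step_protocol"))
  fs <- 10000                       # Hz
  dt <- 1000 / fs                   # ms
  n <- round((protocol$baseline + protocol$step_duration + protocol$tail) / dt)
  # the command switches at t = baseline; the first sample it affects is one
  # interval later, so the emitted sample at the onset time is still baseline
  on_i <- round(protocol$baseline / dt) + 2L
  off_i <- min(on_i + round(protocol$step_duration / dt) - 1L, n)
  refr_steps <- round(params$refractory / dt)
  with_local_seed(seed, {
    sweeps <- vector("list", length(protocol$step_amplitudes))
    logs <- vector("list", length(protocol$step_amplitudes))
    for (k in seq_along(protocol$step_amplitudes)) {
      amp <- protocol$step_amplitudes[k]
      i_cmd <- numeric(n)
      i_cmd[on_i:off_i] <- amp
      if (params$noise_sd > 0) {
        i_cmd <- i_cmd + stats::rnorm(n, 0, params$noise_sd)
      }
      res <- adex_integrate(params, i_cmd, dt, refr_steps)
      if (!all(is.finite(res$v))) {
        stop(sprintf("integration instability at step %g pA", amp),
             call. = FALSE)
      }
      sweeps[[k]] <- fs_sweep(res$v, sampling_rate = fs,
                              stimulus_onset = protocol$baseline,
                              stimulus_duration = protocol$step_duration,
                              stimulus_amplitude = amp,
                              mode = "current_clamp")
      logs[[k]] <- (res$spike_idx - 1) * dt
    }
    rec <- fs_recording(sweeps, cell_id = cell_id)
    attr(rec, "spike_log") <- logs
    rec
  })
}

# Forward-Euler core. Returns emitted voltage trace and spike sample indices.
#
# Once V passes the spike-initiation point (v_t + 3 delta_t) the exponential
# term makes the AdEx trajectory diverge within a fraction of a sample, so
# the unresolved Na+/K+ transient is emitted as a stereotyped, sample-aligned
# waveform: two rise samples to v_peak (the logged spike sample), a two-sample
# repolarization, then v_reset held for the refractory period. This gives
# every spike an identical shape on the sample grid, i.e. well-defined
# ground-truth amplitude, half-width and fAHP for the extractors.
adex_integrate <- function(p, i_cmd, dt, refr_steps) {
  n <- length(i_cmd)
  v_out <- numeric(n)
  spikes <- integer(0)
  hinf <- function(v) 1 / (1 + exp((v + 80) / 8))
  # start from the resting state of the full model (leak + H at h_inf)
  v <- p$e_l
  for (it in 1:50) {
    h0 <- hinf(v)
    v <- (p$g_l * p$e_l + p$g_h * h0 * p$e_h) / (p$g_l + p$g_h * h0)
  }
  h <- hinf(v)
  w <- p$a * (v - p$e_l)
  v_init <- p$v_t + 3 * p$delta_t
  # scripted trajectory relative to v_peak, then v_reset + refractory
  span <- p$v_peak - p$v_reset
  script <- c(p$v_peak - 0.22 * span,   # late upstroke
              p$v_peak,                 # peak (logged spike sample)
              p$v_peak - 0.55 * span,   # fast repolarization
              p$v_peak - 0.87 * span)   # approach to reset
  pend <- numeric(0)                    # pending scripted samples
  refr <- 0L
  for (i in seq_len(n)) {
    if (length(pend) > 0) {
      v_out[i] <- pend[1]
      if (pend[1] == p$v_peak) {
        spikes <- c(spikes, i)
        w <- w + p$b
      }
      pend <- pend[-1]
      if (length(pend) == 0) {
        v <- p$v_reset
        refr <- refr_steps
      }
      h <- h + dt * (hinf(v_out[i]) - h) / p$tau_h
      next
    }
    if (refr > 0L) {
      v_out[i] <- v
      refr <- refr - 1L
      w <- w + dt * (p$a * (v - p$e_l) - w) / p$tau_w
      h <- h + dt * (hinf(v) - h) / p$tau_h
      next
    }
    expterm <- p$g_l * p$delta_t * exp(min((v - p$v_t) / p$delta_t, 30))
    dv <- (-p$g_l * (v - p$e_l) + expterm - w -
             p$g_h * h * (v - p$e_h) + i_cmd[i]) / p$c_m
    v_new <- v + dt * dv
    w <- w + dt * (p$a * (v - p$e_l) - w) / p$tau_w
    h <- h + dt * (hinf(v) - h) / p$tau_h
    if (v_new >= v_init) {
      v_out[i] <- min(v_new, v_init)
      pend <- script
      v <- v_out[i]
    } else {
      v_out[i] <- v_new
      v <- v_new
    }
  }
  list(v = v_out, spike_idx = spikes)
}

#' Ground-truth spike times of a simulated recording
#'
#' @param rec A recording produced by [simulate_current_clamp()].
#' @return List (one element per sweep) of spike times in ms.
#' @export
spike_log <- function(rec) {
  log <- attr(rec, "spike_log")
  if (is.null(log)) {
    stop("recording carries no simulator spike log", call. = FALSE)
  }
  log
}
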