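#' Resting membrane potential
#'
#' Mean of the pre-stimulus baseline over all current-clamp sweeps,
#' emulating the potential read directly after break-in, before any current
#' step is applied.
#'
#' @param rec A current-clamp [fs_recording()] whose sweeps have at least
#'   50 ms of pre-stimulus baseline.
#' @return V_rmp in mV.
#' @export
resting_potential <- function(rec) {
  stopifnot(inherits(rec, "fs_recording"))
  if (length(rec$sweeps) == 0) stop("empty recording", call. = FALSE)
  if (rec$sweeps[[1]]$mode != "current_clamp") {
    stop("resting potential requires a current-clamp recording",
         call. = FALSE)
  }
  onsets <- vapply(rec$sweeps, `[[`, 0, "stimulus_onset")
  if (any(onsets < 50)) {
    stop("each sweep needs >= 50 ms of pre-stimulus baseline", call. = FALSE)
  }
  mean(vapply(rec$sweeps,
              function(s) baseline_window(s, s$stimulus_onset)$mean, 0))
}

# Internal: baseline-relative steady-state deflection over the final
# fraction of the step (default: last 10%, i.e. 50 ms of a 500 ms step).
steady_deflection <- function(sweep, frac = 0.1) {
  base <- baseline_window(sweep, sweep$stimulus_onset)$mean
  mean(sweep$samples[stim_indices(sweep, frac = frac)]) - base
}

#' Input resistance from the steady-state V-I relation
#'
#' Ordinary least-squares slope of the steady-state voltage deflection
#' (mean over the final 10% of the step, relative to the per-sweep baseline)
#' against injected current, over hyperpolarizing and zero-current
#' subthreshold steps. Sweeps containing spikes are excluded with a warning.
#'
#' @param rec A current-clamp [fs_recording()] with at least 3 usable
#'   non-depolarizing steps.
#' @param steady_frac Fraction of the step treated as steady state
#'   (default 0.1).
#' @return R_in in MOhm.
#' @export
input_resistance <- function(rec, steady_frac = 0.1) {
  stopifnot(inherits(rec, "fs_recording"))
  amps <- vapply(rec$sweeps, `[[`, 0, "stimulus_amplitude")
  cand <- which(amps <= 0)
  if (length(cand) > 0) {
    spiking <- vapply(rec$sweeps[cand],
                      function(s) nrow(detect_spikes(s)) > 0, TRUE)
    if (any(spiking)) {
      warning(sprintf("excluding %d spiking sweep(s) from the passive fit",
                      sum(spiking)))
      cand <- cand[!spiking]
    }
  }
  if (length(cand) < 3) {
    stop("input resistance needs >= 3 usable subthreshold steps",
         call. = FALSE)
  }
  dv <- vapply(rec$sweeps[cand], steady_deflection, 0, frac = steady_frac)
  i <- amps[cand]
  slope <- stats::coef(stats::lm(dv ~ i))[["i"]]   # mV/pA = GOhm
  1000 * slope                                     # MOhm
}

#' Membrane time constant from a -100 pA step
#'
#' Averages all -100 pA sweeps, then fits
#' `V(t) = V0 + dV * (1 - exp(-(t - onset)/tau))` by least squares to the
#' rising (hyperpolarizing) phase restricted to the segment from stimulus
#' onset until the mean trace first reaches 63.2% of its steady-state
#' deflection.
#'
#' @param rec A current-clamp [fs_recording()] containing at least one
#'   -100 pA step.
#' @param step_amplitude Step used for the fit, pA (default -100).
#' @return tau_m in ms.
#' @export
membrane_time_constant <- function(rec, step_amplitude = -100) {
  stopifnot(inherits(rec, "fs_recording"))
  sw <- sweeps_at(rec, step_amplitude)
  if (length(sw) == 0) {
    stop(sprintf("no %g pA sweep in recording", step_amplitude),
         call. = FALSE)
  }
  avg <- sw[[1]]
  if (length(sw) > 1) {
    avg$samples <- rowMeans(vapply(sw, `[[`,
                                   numeric(length(sw[[1]]$samples)),
                                   "samples"))
  }
  v0 <- baseline_window(avg, avg$stimulus_onset)$mean
  dv_ss <- steady_deflection(avg)
  t <- sweep_times(avg)
  idx_step <- stim_indices(avg)
  if (abs(dv_ss) < 0.5) {
    stop("degenerate step: no measurable voltage deflection to fit",
         call. = FALSE)
  }
  # segment: onset up to the first crossing of 63.2% of the steady deflection
  target <- v0 + (1 - exp(-1)) * dv_ss
  rel <- avg$samples[idx_step]
  crossed <- if (dv_ss < 0) which(rel <= target) else which(rel >= target)
  if (length(crossed) == 0) {
    stop("trace never reaches 63.2% of its steady-state deflection",
         call. = FALSE)
  }
  seg <- idx_step[seq_len(max(crossed[1], 5L))]
  df <- data.frame(ts = t[seg] - avg$stimulus_onset, v = avg$samples[seg])
  tau0 <- max(t[seg[crossed[1]]] - avg$stimulus_onset, 2 * (t[2] - t[1]))
  # v0 and dV are pinned to their long-window estimates (baseline and
  # final-10% means); tau is the single free parameter, which keeps the fit
  # well conditioned on the short 0-63.2% segment.
  fit <- tryCatch(
    stats::nls(v ~ v0 + dv_ss * (1 - exp(-ts / tau)), data = df,
               start = list(tau = tau0),
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE),
               algorithm = "port", lower = list(tau = tau0 / 100)),
    error = function(e) {
      stop(sprintf("exponential fit failed: %s (v0=%.2f, dV=%.2f, tau0=%.2f)",
                   conditionMessage(e), v0, dv_ss, tau0), call. = FALSE)
    }
  )
  tau <- stats::coef(fit)[["tau"]]
  if (!is.finite(tau) || tau <= 0) {
    stop("exponential fit returned a non-positive time constant",
         call. = FALSE)
  }
  tau
}

#' Sag ratio of the -100 pA response
#'
#' `V_steady / V_hyp`: the baseline-relative steady-state deflection at the
#' end of the step divided by the peak hyperpolarizing deflection. Both are
#' negative, so the ratio is positive; a ratio below 1 indicates an
#' H-current-mediated depolarizing sag. Ratios marginally above 1 (sampling
#' noise) are clipped to 1 with a warning.
#'
#' @param rec A current-clamp [fs_recording()] with a -100 pA step.
#' @param step_amplitude Step used, pA (default -100).
#' @return Dimensionless sag ratio in (0, 1].
#' @export
sag_ratio <- function(rec, step_amplitude = -100) {
  stopifnot(inherits(rec, "fs_recording"))
  sw <- sweeps_at(rec, step_amplitude)
  if (length(sw) == 0) {
    stop(sprintf("no %g pA sweep in recording", step_amplitude),
         call. = FALSE)
  }
  avg <- sw[[1]]
  if (length(sw) > 1) {
    avg$samples <- rowMeans(vapply(sw, `[[`,
                                   numeric(length(sw[[1]]$samples)),
                                   "samples"))
  }
  base <- baseline_window(avg, avg$stimulus_onset)$mean
  v_steady <- steady_deflection(avg)
  v_hyp <- min(avg$samples[stim_indices(avg)]) - base
  if (v_hyp >= 0 || v_steady >= 0) {
    stop("no hyperpolarizing deflection: sag ratio undefined", call. = FALSE)
  }
  ratio <- v_steady / v_hyp
  if (ratio > 1) {
    warning(sprintf("sag ratio %.4f > 1 clipped to 1", ratio))
    ratio <- 1
  }
  ratio
}

#' Derived membrane capacitance
#'
#' `C = tau_m / R_in`, reconciled to pF (tau in ms, R in MOhm). This is a
#' derived quantity, not an amplifier capacitance readout, and is labelled
#' as such in reports.
#'
#' @param tau_m Membrane time constant, ms.
#' @param r_in Input resistance, MOhm.
#' @return C_mem in pF.
#' @export
capacitance <- function(tau_m, r_in) {
  if (!is.finite(tau_m) || tau_m <= 0) stop("tau_m must be positive",
                                            call. = FALSE)
  if (!is.finite(r_in) || r_in <= 0) stop("r_in must be positive",
                                          call. = FALSE)
  1000 * tau_m / r_in
}

#' Extract all passive membrane properties
#'
#' Convenience wrapper running [resting_potential()], [input_resistance()],
#' [membrane_time_constant()], [sag_ratio()] and [capacitance()] on one
#' current-step recording.
#'
#' @param rec A current-clamp [fs_recording()] from a step protocol
#'   including hyperpolarizing steps and a -100 pA step.
#' @return An object of class `fs_passive` with fields `v_rmp` (mV), `r_in`
#'   (MOhm), `tau_m` (ms), `sag_ratio`, `c_mem` (pF, derived).
#' @export
passive_properties <- function(rec) {
  r_in <- input_resistance(rec)
  tau_m <- membrane_time_constant(rec)
  structure(
    list(v_rmp = resting_potential(rec), r_in = r_in, tau_m = tau_m,
         sag_ratio = sag_ratio(rec), c_mem = capacitance(tau_m, r_in)),
    class = "fs_passive"
  )
}

#' @export
print.fs_passive <- function(x, ...) {
  cat("Passive membrane properties\n")
  cat(sprintf("  V_rmp      %8.1f mV\n", x$v_rmp))
  cat(sprintf("  R_in       %8.1f MOhm\n", x$r_in))
  cat(sprintf("  tau_m      %8.2f ms\n", x$tau_m))
  cat(sprintf("  Sag ratio  %8.3f\n", x$sag_ratio))
  cat(sprintf("  C_mem      %8.1f pF (derived: tau_m / R_in)\n", x$c_mem))
  invisible(x)
}

#' @export
as.data.frame.fs_passive <- function(x, ...) {
  data.frame(v_rmp = x$v_rmp, r_in = x$r_in, tau_m = x$tau_m,
             sag_ratio = x$sag_ratio, c_mem = x$c_mem)
}
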