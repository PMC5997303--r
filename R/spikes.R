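#' Detect action potentials in a current-clamp sweep
#'
#' Candidate spikes are local voltage maxima exceeding -10 mV that are
#' preceded within 2 ms by a membrane-potential derivative of at least
#' 20 V/s (central differences at native sampling). Detections closer than
#' 1 ms to an accepted spike are discarded (refractory rule), keeping the
#' earlier one.
#'
#' @param sweep A current-clamp [fs_sweep()].
#' @param peak_floor Minimum peak voltage, mV (default -10).
#' @param dvdt_min Minimum pre-peak derivative, V/s (default 20).
#' @param min_separation Minimum inter-spike separation, ms (default 1).
#' @return Data frame with columns `peak_t` (ms) and `peak_v` (mV), ordered
#'   in time; zero rows for a silent sweep.
#' @export
detect_spikes <- function(sweep, peak_floor = -10, dvdt_min = 20,
                          min_separation = 1) {
  stopifnot(inherits(sweep, "fs_sweep"))
  if (sweep$mode != "current_clamp") {
    stop("spike detection requires a current-clamp sweep", call. = FALSE)
  }
  v <- sweep$samples
  n <- length(v)
  empty <- data.frame(peak_t = numeric(0), peak_v = numeric(0))
  if (n < 3) return(empty)
  dt <- 1000 / sweep$sampling_rate
  core <- 2:(n - 1)
  is_max <- v[core] > v[core + 1] & v[core] >= v[core - 1]
  cand <- core[is_max & v[core] > peak_floor]
  if (length(cand) == 0) return(empty)
  d <- dvdt(v, dt)                      # mV/ms == V/s
  back <- max(1L, round(2 / dt))
  ok <- vapply(cand, function(i) {
    lo <- max(1L, i - back)
    any(d[lo:i] >= dvdt_min)
  }, TRUE)
  cand <- cand[ok]
  if (length(cand) == 0) return(empty)
  keep <- cand[1]
  for (i in cand[-1]) {
    if ((i - keep[length(keep)]) * dt >= min_separation) keep <- c(keep, i)
  }
  data.frame(peak_t = (keep - 1) * dt, peak_v = v[keep])
}

# Central-difference derivative in mV/ms; one-sided at the ends.
dvdt <- function(v, dt) {
  n <- length(v)
  d <- numeric(n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt)
  d[1] <- (v[2] - v[1]) / dt
  d[n] <- (v[n] - v[n - 1]) / dt
  d
}

#' Action-potential threshold (20 V/s criterion)
#'
#' The threshold is the membrane potential at which dV/dt first reaches
#' 20 V/s on the upstroke: searching backward from the peak, the algorithm
#' finds the last sample whose central-difference derivative is below the
#' criterion, then steps one sample forward.
#'
#' @param sweep A current-clamp [fs_sweep()].
#' @param peak_t Peak time of a detected spike, ms (from [detect_spikes()]).
#' @param dvdt_min Threshold derivative, V/s (default 20).
#' @return List with `threshold_v` (mV) and `threshold_t` (ms).
#' @export
ap_threshold <- function(sweep, peak_t, dvdt_min = 20) {
  stopifnot(inherits(sweep, "fs_sweep"))
  dt <- 1000 / sweep$sampling_rate
  ip <- round(peak_t / dt) + 1L
  v <- sweep$samples
  if (ip < 3 || ip > length(v)) stop("peak time outside sweep",
                                     call. = FALSE)
  d <- dvdt(v, dt)
  if (!any(d[2:(ip - 1)] >= dvdt_min)) {
    stop(sprintf("dV/dt never reaches %g V/s before the peak at %g ms",
                 dvdt_min, peak_t), call. = FALSE)
  }
  i <- ip - 1L
  while (i > 1L && d[i] < dvdt_min) i <- i - 1L   # skip to the upstroke run
  while (i > 1L && d[i] >= dvdt_min) i <- i - 1L  # walk to its start
  it <- i + 1L
  list(threshold_v = v[it], threshold_t = (it - 1) * dt)
}

#' Action-potential amplitude
#'
#' Peak voltage relative to the threshold voltage.
#'
#' @param peak_v Peak voltage, mV.
#' @param threshold_v Threshold voltage, mV.
#' @return Amplitude in mV.
#' @export
ap_amplitude <- function(peak_v, threshold_v) {
  peak_v - threshold_v
}

#' Action-potential half-width
#'
#' Duration at the voltage halfway between threshold and peak, measured
#' between the rising and falling crossings of that level with linear
#' interpolation between samples (sampling at 0.1 ms is coarse relative to
#' sub-millisecond half-widths).
#'
#' @param sweep A current-clamp [fs_sweep()].
#' @param peak_t Spike peak time, ms.
#' @param threshold_v Threshold voltage, mV.
#' @param search_ms How far around the peak to search for crossings, ms.
#' @return Half-width in ms.
#' @export
ap_half_width <- function(sweep, peak_t, threshold_v, search_ms = 10) {
  stopifnot(inherits(sweep, "fs_sweep"))
  v <- sweep$samples
  dt <- 1000 / sweep$sampling_rate
  ip <- round(peak_t / dt) + 1L
  half <- threshold_v + (v[ip] - threshold_v) / 2
  span <- max(1L, round(search_ms / dt))
  # rising crossing: last upward crossing of the half level before the peak
  lo <- max(2L, ip - span)
  rise <- NA_real_
  for (i in seq(ip, lo, by = -1L)) {
    if (v[i - 1] < half && v[i] >= half) {
      frac <- (half - v[i - 1]) / (v[i] - v[i - 1])
      rise <- (i - 2L + frac) * dt
      break
    }
  }
  if (is.na(rise)) {
    stop("no rising half-level crossing found before the peak",
         call. = FALSE)
  }
  hi <- min(length(v) - 1L, ip + span)
  fall <- NA_real_
  for (i in seq(ip, hi, by = 1L)) {
    if (v[i] >= half && v[i + 1] < half) {
      frac <- (v[i] - half) / (v[i] - v[i + 1])
      fall <- (i - 1L + frac) * dt
      break
    }
  }
  if (is.na(fall)) {
    stop("spike truncated: no falling half-level crossing", call. = FALSE)
  }
  fall - rise
}

#' Action-potential latency
#'
#' Time from current onset to the peak of the first evoked spike.
#'
#' @param peak_t Peak time of the first spike, ms.
#' @param stimulus_onset Step onset, ms.
#' @return Latency in ms.
#' @export
ap_latency <- function(peak_t, stimulus_onset) {
  if (peak_t < stimulus_onset) {
    stop("spike peak precedes stimulus onset", call. = FALSE)
  }
  peak_t - stimulus_onset
}

#' Fast after-hyperpolarization
#'
#' Trough following the spike peak, searched up to the next spike (or 10 ms
#' for the last spike). Amplitude is measured relative to the threshold
#' voltage; latency from the threshold-crossing time on the rising phase to
#' the trough. A spike with no undershoot below threshold gets amplitude 0
#' and is flagged.
#'
#' @param sweep A current-clamp [fs_sweep()].
#' @param peak_t Spike peak time, ms.
#' @param threshold_v,threshold_t Threshold voltage (mV) and time (ms).
#' @param next_spike_t Peak time of the following spike, ms, or `NULL`.
#' @return List with `amplitude` (mV, >= 0), `latency` (ms, NA when
#'   flagged) and `flagged` (no undershoot found).
#' @export
fahp <- function(sweep, peak_t, threshold_v, threshold_t,
                 next_spike_t = NULL) {
  stopifnot(inherits(sweep, "fs_sweep"))
  v <- sweep$samples
  dt <- 1000 / sweep$sampling_rate
  ip <- round(peak_t / dt) + 1L
  t_end <- if (is.null(next_spike_t)) peak_t + 10 else next_spike_t
  ie <- min(length(v), round(t_end / dt) + 1L)
  if (ie <= ip + 1L) {
    return(list(amplitude = 0, latency = NA_real_, flagged = TRUE))
  }
  seg <- (ip + 1L):ie
  imin <- seg[which.min(v[seg])]
  trough_v <- v[imin]
  if (trough_v >= threshold_v) {
    return(list(amplitude = 0, latency = NA_real_, flagged = TRUE))
  }
  list(amplitude = threshold_v - trough_v,
       latency = (imin - 1) * dt - threshold_t,
       flagged = FALSE)
}

#' Measure all single-spike features
#'
#' @param sweep A current-clamp [fs_sweep()].
#' @param peak_t Spike peak time, ms.
#' @param next_spike_t Peak time of the following spike, ms, or `NULL`.
#' @return A one-row data frame: `threshold_v`, `threshold_t`, `peak_v`,
#'   `peak_t`, `amplitude`, `half_width`, `latency`, `fahp_amplitude`,
#'   `fahp_latency`, `fahp_flagged`.
#' @export
measure_spike <- function(sweep, peak_t, next_spike_t = NULL) {
  thr <- ap_threshold(sweep, peak_t)
  dt <- 1000 / sweep$sampling_rate
  peak_v <- sweep$samples[round(peak_t / dt) + 1L]
  hw <- ap_half_width(sweep, peak_t, thr$threshold_v)
  ah <- fahp(sweep, peak_t, thr$threshold_v, thr$threshold_t, next_spike_t)
  data.frame(
    threshold_v = thr$threshold_v, threshold_t = thr$threshold_t,
    peak_v = peak_v, peak_t = peak_t,
    amplitude = ap_amplitude(peak_v, thr$threshold_v),
    half_width = hw,
    latency = ap_latency(peak_t, sweep$stimulus_onset),
    fahp_amplitude = ah$amplitude, fahp_latency = ah$latency,
    fahp_flagged = ah$flagged
  )
}

# Internal: lowest-amplitude step in [lo, hi] pA eliciting >= 1 spike.
# Returns list(sweep, spikes, amplitude) or NULL.
first_evoked_step <- function(rec, lo = 20, hi = 100) {
  amps <- vapply(rec$sweeps, `[[`, 0, "stimulus_amplitude")
  ord <- order(amps)
  for (k in ord) {
    if (amps[k] < lo - 1e-9 || amps[k] > hi + 1e-9) next
    sp <- detect_spikes(rec$sweeps[[k]])
    if (nrow(sp) > 0) {
      return(list(sweep = rec$sweeps[[k]], spikes = sp, amplitude = amps[k]))
    }
  }
  NULL
}

#' Features of the first evoked action potential
#'
#' Selects the lowest-amplitude step in the 20-100 pA series eliciting at
#' least one spike and measures its first spike; this spike supplies all
#' single-AP entries of a feature report.
#'
#' @param rec A current-clamp [fs_recording()] containing the 20-100 pA
#'   series (any recording whose step amplitudes cover that range works).
#' @return A one-row data frame as from [measure_spike()], plus
#'   `step_amplitude`; `NULL` when no step in the series evokes a spike.
#' @export
first_ap_features <- function(rec) {
  hit <- first_evoked_step(rec)
  if (is.null(hit)) return(NULL)
  nxt <- if (nrow(hit$spikes) > 1) hit$spikes$peak_t[2] else NULL
  out <- measure_spike(hit$sweep, hit$spikes$peak_t[1], nxt)
  out$step_amplitude <- hit$amplitude
  out
}
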