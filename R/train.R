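#' Spike-frequency accommodation and amplitude attenuation
#'
#' Compares the last 100 ms of a step against the first 100 ms:
#' `adaptation_ratio` is the late/early firing-rate ratio (1 = no
#' accommodation), `amplitude_attenuation` is the fractional loss of mean
#' spike amplitude (0 = none). These are summary metrics for the
#' qualitative phenomenon of late-train slowing and amplitude run-down, and
#' are flagged as derived (non-tabulated) quantities in reports.
#'
#' @param sweep A current-clamp [fs_sweep()] with a step of at least 200 ms
#'   and at least 4 detected spikes.
#' @param window Comparison window, ms (default 100).
#' @return List with `adaptation_ratio` and `amplitude_attenuation`;
#'   both `NA` when fewer than 4 spikes are present.
#' @export
accommodation_metrics <- function(sweep, window = 100) {
  stopifnot(inherits(sweep, "fs_sweep"))
  sp <- detect_spikes(sweep)
  na <- list(adaptation_ratio = NA_real_, amplitude_attenuation = NA_real_)
  if (nrow(sp) < 4) return(na)
  on <- sweep$stimulus_onset
  off <- on + sweep$stimulus_duration
  early <- sp$peak_t >= on & sp$peak_t < on + window
  late <- sp$peak_t >= off - window & sp$peak_t < off
  if (sum(early) == 0) return(na)
  amp_of <- function(idx) {
    vapply(idx, function(i) {
      thr <- ap_threshold(sweep, sp$peak_t[i])
      sp$peak_v[i] - thr$threshold_v
    }, 0)
  }
  att <- if (sum(late) == 0) 1 else {
    1 - mean(amp_of(which(late))) / mean(amp_of(which(early)))
  }
  list(adaptation_ratio = sum(late) / sum(early),
       amplitude_attenuation = att)
}

#' Train features of one step sweep
#'
#' @param sweep A current-clamp [fs_sweep()].
#' @return One-row data frame: `step_amplitude` (pA), `spike_count`,
#'   `firing_rate` (Hz over the step window), `adaptation_ratio`,
#'   `amplitude_attenuation`.
#' @export
train_features <- function(sweep) {
  stopifnot(inherits(sweep, "fs_sweep"))
  sp <- detect_spikes(sweep)
  on <- sweep$stimulus_onset
  off <- on + sweep$stimulus_duration
  n_in <- sum(sp$peak_t >= on & sp$peak_t < off)
  acc <- accommodation_metrics(sweep)
  data.frame(step_amplitude = sweep$stimulus_amplitude,
             spike_count = n_in,
             firing_rate = n_in / (sweep$stimulus_duration / 1000),
             adaptation_ratio = acc$adaptation_ratio,
             amplitude_attenuation = acc$amplitude_attenuation)
}

#' Action-potential broadening
#'
#' `(HW2 - HW1) / HW1`, the fractional half-width increase from the first to
#' the second spike, measured on the step at twice the current of the first
#' evoked AP. When that exact step is absent the nearest available amplitude
#' is used with a warning.
#'
#' @param rec A current-clamp [fs_recording()] providing the larger steps on
#'   which the two half-widths are measured.
#' @param first_ap_rec Recording providing the 20-100 pA first-AP series;
#'   defaults to `rec`.
#' @return Dimensionless broadening, or `NA` when no step evokes a first AP
#'   or the target step has fewer than 2 spikes.
#' @export
ap_broadening <- function(rec, first_ap_rec = rec) {
  hit <- first_evoked_step(first_ap_rec)
  if (is.null(hit)) return(NA_real_)
  target <- 2 * hit$amplitude
  amps <- vapply(rec$sweeps, `[[`, 0, "stimulus_amplitude")
  k <- which.min(abs(amps - target))
  if (abs(amps[k] - target) > 1e-6) {
    warning(sprintf(
      "no %g pA step (2x first-AP current); using nearest step %g pA",
      target, amps[k]))
  }
  sweep <- rec$sweeps[[k]]
  sp <- detect_spikes(sweep)
  if (nrow(sp) < 2) return(NA_real_)
  thr1 <- ap_threshold(sweep, sp$peak_t[1])
  thr2 <- ap_threshold(sweep, sp$peak_t[2])
  hw1 <- ap_half_width(sweep, sp$peak_t[1], thr1$threshold_v)
  hw2 <- ap_half_width(sweep, sp$peak_t[2], thr2$threshold_v)
  (hw2 - hw1) / hw1
}

# Internal: does a step sweep show AP failures? Either an aborted spike
# (a local maximum between spikes that exceeds the spikes' threshold level
# but misses the -10 mV detection bar) or cessation of spiking over the
# last 100 ms of the step despite earlier spikes (depolarization block).
step_has_failures <- function(sweep, spikes) {
  if (nrow(spikes) == 0) return(FALSE)
  on <- sweep$stimulus_onset
  off <- on + sweep$stimulus_duration
  if (!any(spikes$peak_t >= off - 100) && sweep$stimulus_duration >= 200) {
    return(TRUE)
  }
  thr <- mean(vapply(seq_len(min(nrow(spikes), 3L)), function(i) {
    tryCatch(ap_threshold(sweep, spikes$peak_t[i])$threshold_v,
             error = function(e) NA_real_)
  }, 0), na.rm = TRUE)
  if (!is.finite(thr)) return(FALSE)
  v <- sweep$samples
  dt <- 1000 / sweep$sampling_rate
  core <- 2:(length(v) - 1)
  ismax <- v[core] > v[core + 1] & v[core] >= v[core - 1]
  tmax <- (core[ismax] - 1) * dt
  vmax <- v[core[ismax]]
  aborted <- vmax > thr & vmax <= -10 & tmax >= on & tmax < off &
    !(tmax %in% spikes$peak_t)
  any(aborted)
}

#' Maximal firing frequency
#'
#' Firing rate on the largest depolarizing step below the first step showing
#' AP failures (aborted spikes between full spikes, or cessation of spiking
#' over the last 100 ms of the step). With no failing step, the largest
#' spiking step qualifies.
#'
#' @param rec A current-clamp [fs_recording()] from a full step protocol.
#' @return Maximal firing frequency in Hz, or `NA` when no step spikes.
#' @export
max_firing_frequency <- function(rec) {
  max_rate_step(rec)$rate
}

# Internal: qualifying step for the maximal firing frequency.
max_rate_step <- function(rec) {
  stopifnot(inherits(rec, "fs_recording"))
  amps <- vapply(rec$sweeps, `[[`, 0, "stimulus_amplitude")
  ord <- order(amps)
  ord <- ord[amps[ord] > 0]
  best <- list(rate = NA_real_, index = NA_integer_)
  for (k in ord) {
    sweep <- rec$sweeps[[k]]
    sp <- detect_spikes(sweep)
    on <- sweep$stimulus_onset
    n_in <- sum(sp$peak_t >= on & sp$peak_t < on + sweep$stimulus_duration)
    if (n_in == 0) next
    if (step_has_failures(sweep, sp)) break
    best <- list(rate = n_in / (sweep$stimulus_duration / 1000), index = k)
  }
  best
}

#' Population I-f curve
#'
#' Firing rate versus injected current: spike counts over the 500 ms step
#' window, averaged across cells per current amplitude. Cells not tested at
#' a given amplitude are omitted from that point, so `n` varies along the
#' curve.
#'
#' @param recs A single [fs_recording()] or a list of them (one per cell).
#' @param min_current Smallest current included, pA (default 0: depolarizing
#'   steps and the zero-current step).
#' @return An object of class `fs_if_curve`: a data frame with `current`
#'   (pA), `mean_rate` and `sd_rate` (Hz) and `n` (cells per point), sorted
#'   by current.
#' @export
if_curve <- function(recs, min_current = 0) {
  if (inherits(recs, "fs_recording")) recs <- list(recs)
  if (length(recs) == 0 ||
      !all(vapply(recs, inherits, TRUE, "fs_recording"))) {
    stop("if_curve needs one or more fs_recording objects", call. = FALSE)
  }
  rows <- do.call(rbind, lapply(seq_along(recs), function(ci) {
    rec <- recs[[ci]]
    amps <- vapply(rec$sweeps, `[[`, 0, "stimulus_amplitude")
    keep <- which(amps >= min_current)
    if (length(keep) == 0) return(NULL)
    do.call(rbind, lapply(keep, function(k) {
      sweep <- rec$sweeps[[k]]
      sp <- detect_spikes(sweep)
      on <- sweep$stimulus_onset
      n_in <- sum(sp$peak_t >= on & sp$peak_t < on + sweep$stimulus_duration)
      data.frame(cell = ci, current = amps[k],
                 rate = n_in / (sweep$stimulus_duration / 1000))
    }))
  }))
  if (is.null(rows) || nrow(rows) == 0) {
    stop("no depolarizing steps found in input", call. = FALSE)
  }
  agg <- do.call(rbind, lapply(split(rows, rows$current), function(g) {
    data.frame(current = g$current[1], mean_rate = mean(g$rate),
               sd_rate = if (nrow(g) > 1) stats::sd(g$rate) else NA_real_,
               n = nrow(g))
  }))
  agg <- agg[order(agg$current), ]
  rownames(agg) <- NULL
  structure(agg, class = c("fs_if_curve", "data.frame"))
}

#' @export
print.fs_if_curve <- function(x, ...) {
  cat(sprintf("I-f curve: %d current levels, %g..%g pA, peak mean rate %.1f Hz\n",
              nrow(x), min(x$current), max(x$current), max(x$mean_rate)))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot an I-f curve
#'
#' Mean firing rate against injected current with +/- 1 sd error bars.
#'
#' @param x An [if_curve()] result.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.fs_if_curve <- function(x, ...) {
  graphics::plot(x$current, x$mean_rate, type = "b", pch = 16,
                 xlab = "injected current (pA)", ylab = "firing rate (Hz)",
                 ...)
  has_sd <- !is.na(x$sd_rate)
  if (any(has_sd)) {
    graphics::arrows(x$current[has_sd], x$mean_rate[has_sd] - x$sd_rate[has_sd],
                     x$current[has_sd], x$mean_rate[has_sd] + x$sd_rate[has_sd],
                     angle = 90, code = 3, length = 0.03)
  }
  invisible(x)
}

#' Full electrophysiological characterization of one cell
#'
#' Runs the passive and spike pipelines on a pair of recordings and
#' assembles a feature report in the layout of a standard intrinsic-property
#' table.
#'
#' @param step_rec Recording from the full step protocol (-100..1500 pA).
#' @param first_ap_rec Recording from the 20-100 pA first-AP series;
#'   defaults to `step_rec` (usable when its increments cover that range).
#' @return An object of class `fs_cell_report`: list with `passive`
#'   ([fs_passive]), `first_ap` (single-AP features), `broadening`,
#'   `max_firing_frequency`, `if_curve`, and `accommodation` (metrics on the
#'   maximal-frequency step).
#' @export
characterize_cell <- function(step_rec, first_ap_rec = step_rec) {
  passive <- passive_properties(step_rec)
  first_ap <- first_ap_features(first_ap_rec)
  broad <- suppressWarnings(ap_broadening(step_rec, first_ap_rec))
  mrs <- max_rate_step(step_rec)
  ifc <- if_curve(step_rec)
  acc <- NULL
  if (is.finite(mrs$index)) {
    acc <- accommodation_metrics(step_rec$sweeps[[mrs$index]])
  }
  structure(list(passive = passive, first_ap = first_ap, broadening = broad,
                 max_firing_frequency = mrs$rate, if_curve = ifc,
                 accommodation = acc, cell_id = step_rec$cell_id),
            class = "fs_cell_report")
}

#' @export
print.fs_cell_report <- function(x, ...) {
  cat(sprintf("Electrophysiological properties of cell '%s'\n", x$cell_id))
  print(x$passive)
  if (!is.null(x$first_ap)) {
    f <- x$first_ap
    cat(sprintf("First evoked AP (at %g pA)\n", f$step_amplitude))
    cat(sprintf("  AP threshold   %8.1f mV\n", f$threshold_v))
    cat(sprintf("  AP latency     %8.1f ms\n", f$latency))
    cat(sprintf("  AP amplitude   %8.1f mV\n", f$amplitude))
    cat(sprintf("  AP half-width  %8.2f ms\n", f$half_width))
    cat(sprintf("  fAHP amplitude %8.1f mV%s\n", f$fahp_amplitude,
                if (f$fahp_flagged) " (no undershoot)" else ""))
    if (!f$fahp_flagged) {
      cat(sprintf("  fAHP latency   %8.2f ms\n", f$fahp_latency))
    }
  } else {
    cat("First evoked AP: none detected in the 20-100 pA series\n")
  }
  if (is.finite(x$broadening)) {
    cat(sprintf("  AP broadening  %8.3f\n", x$broadening))
  }
  cat(sprintf("  Max firing frequency %6.1f Hz\n", x$max_firing_frequency))
  if (!is.null(x$accommodation) &&
      is.finite(x$accommodation$adaptation_ratio)) {
    cat(sprintf("  Adaptation ratio (derived)       %6.2f\n",
                x$accommodation$adaptation_ratio))
    cat(sprintf("  Amplitude attenuation (derived)  %6.2f\n",
                x$accommodation$amplitude_attenuation))
  }
  invisible(x)
}
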