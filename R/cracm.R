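#' Average consecutive light-aligned sweeps
#'
#' Pointwise mean of the first `n` sweeps of a voltage-clamp recording,
#' preserving the stimulus metadata. Averaging ten consecutive sweeps is the
#' conventional preprocessing before measuring a light-evoked response.
#'
#' @param rec A voltage-clamp [fs_recording()] whose sweeps share light-onset
#'   metadata.
#' @param n Number of sweeps to average (default 10). When fewer are
#'   available all sweeps are used with a warning.
#' @return An [fs_sweep()] containing the averaged trace.
#' @export
average_aligned_sweeps <- function(rec, n = 10) {
  stopifnot(inherits(rec, "fs_recording"))
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  if (length(rec$sweeps) == 0) stop("empty recording", call. = FALSE)
  onsets <- vapply(rec$sweeps, `[[`, 0, "stimulus_onset")
  if (length(unique(onsets)) > 1L) {
    stop("sweeps have differing light-onset metadata", call. = FALSE)
  }
  if (length(rec$sweeps) < n) {
    warning(sprintf("only %d sweeps available; averaging all of them",
                    length(rec$sweeps)))
    n <- length(rec$sweeps)
  }
  sw <- rec$sweeps[seq_len(n)]
  avg <- sw[[1]]
  avg$samples <- rowMeans(vapply(sw, `[[`, numeric(length(sw[[1]]$samples)),
                                 "samples"))
  avg
}

#' Measure a light-evoked EPSC on an averaged sweep
#'
#' Baseline is the 50 ms pre-light mean. The amplitude is the drop from
#' baseline to the trace minimum inside the monosynaptic detection window
#' (1-20 ms after light onset), reported as a positive magnitude of the
#' inward (negative) current. Onset latency is the first post-light time the
#' trace deviates more than 3 baseline standard deviations below baseline.
#' The measurement is classified with [classify_connected()].
#'
#' @param avg An averaged voltage-clamp [fs_sweep()] (see
#'   [average_aligned_sweeps()]).
#' @param window Detection window after light onset, ms (default `c(1, 20)`).
#' @param n_sweeps_averaged Bookkeeping: number of sweeps behind `avg`.
#' @return An object of class `fs_epsc`: `mean_amplitude` (pA),
#'   `onset_latency` (ms, NA when never past 3 sd), `baseline_sd` (pA),
#'   `n_sweeps_averaged`, `connected`.
#' @export
measure_epsc <- function(avg, window = c(1, 20), n_sweeps_averaged = 1) {
  stopifnot(inherits(avg, "fs_sweep"))
  if (avg$mode != "voltage_clamp") {
    stop("EPSC measurement requires a voltage-clamp sweep", call. = FALSE)
  }
  t <- sweep_times(avg)
  on <- avg$stimulus_onset
  if (sweep_duration(avg) < on + window[2]) {
    stop("sweep ends before the post-light detection window", call. = FALSE)
  }
  base <- baseline_window(avg, 50)
  win <- which(t >= on + window[1] & t <= on + window[2])
  amp <- base$mean - min(avg$samples[win])
  amp <- max(amp, 0)
  post <- which(t >= on & t <= on + window[2])
  dev <- which(avg$samples[post] < base$mean - 3 * base$sd)
  latency <- if (length(dev) > 0) t[post[dev[1]]] - on else NA_real_
  m <- structure(
    list(mean_amplitude = amp, onset_latency = latency,
         baseline_sd = base$sd, n_sweeps_averaged = n_sweeps_averaged,
         connected = NA),
    class = "fs_epsc"
  )
  m$connected <- classify_connected(m)
  m
}

#' @export
print.fs_epsc <- function(x, ...) {
  cat(sprintf(
    "EPSC: %.1f pA (baseline sd %.2f pA, %d sweeps averaged), latency %s -> %s\n",
    x$mean_amplitude, x$baseline_sd, x$n_sweeps_averaged,
    if (is.na(x$onset_latency)) "n/a" else sprintf("%.1f ms", x$onset_latency),
    if (x$connected) "connected" else "not connected"))
  invisible(x)
}

#' Classify a cell as synaptically connected
#'
#' A cell counts as connected when the averaged EPSC amplitude strictly
#' exceeds both an absolute floor (4 pA) and 5 baseline standard deviations
#' of the averaged trace. The criterion is the package's own (configurable)
#' rule; residual currents under glutamatergic block (~2.5 pA) classify as
#' unconnected under the defaults.
#'
#' @param m An `fs_epsc` measurement.
#' @param floor_pa Absolute amplitude floor, pA (default 4).
#' @param sd_mult Baseline-sd multiplier (default 5).
#' @return Logical.
#' @export
classify_connected <- function(m, floor_pa = 4, sd_mult = 5) {
  stopifnot(inherits(m, "fs_epsc"))
  m$mean_amplitude > max(floor_pa, sd_mult * m$baseline_sd)
}

#' Pharmacological block ratio
#'
#' Ratio of the blocked to the control EPSC amplitude from the same cell;
#' a value near 0 confirms the current is glutamatergic.
#'
#' @param control,blocked `fs_epsc` measurements (or bare amplitudes in pA)
#'   before and during antagonist application.
#' @return Dimensionless ratio; `NA` when the control amplitude is 0.
#' @export
block_ratio <- function(control, blocked) {
  amp <- function(x) if (inherits(x, "fs_epsc")) x$mean_amplitude
                     else as.numeric(x)
  a_ctrl <- amp(control)
  a_blk <- amp(blocked)
  if (a_ctrl == 0) return(NA_real_)
  a_blk / a_ctrl
}

#' Population connectivity summary
#'
#' Counts connected cells, the connected percentage, and an exact
#' (Clopper-Pearson) 95% binomial confidence interval.
#'
#' @param flags Logical vector, one entry per tested cell.
#' @return An object of class `fs_connectivity`: `n_connected`, `n_tested`,
#'   `fraction_percent` (to 2 decimals), `ci95` (percent).
#' @export
connectivity_summary <- function(flags) {
  if (length(flags) == 0 || !is.logical(flags) || anyNA(flags)) {
    stop("flags must be a non-empty logical vector without NA",
         call. = FALSE)
  }
  k <- sum(flags)
  n <- length(flags)
  ci <- stats::binom.test(k, n)$conf.int
  structure(
    list(n_connected = k, n_tested = n,
         fraction_percent = round(100 * k / n, 2),
         ci95 = 100 * as.numeric(ci)),
    class = "fs_connectivity"
  )
}

#' @export
print.fs_connectivity <- function(x, ...) {
  cat(sprintf(
    "Connectivity: %d / %d cells (%.2f%% connected; 95%% CI %.2f-%.2f%%)\n",
    x$n_connected, x$n_tested, x$fraction_percent, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' One-cell CRACM analysis
#'
#' Averages the first `n` sweeps of the control (and optionally blocked)
#' recording, measures the light-evoked EPSC in each, and reports the block
#' ratio.
#'
#' @param control Voltage-clamp [fs_recording()] before antagonists.
#' @param blocked Optional recording during glutamate-receptor block.
#' @param n Sweeps to average (default 10).
#' @return List with `control` (`fs_epsc`), `blocked` (`fs_epsc` or NULL)
#'   and `block_ratio` (NA without a blocked recording).
#' @export
cracm_cell <- function(control, blocked = NULL, n = 10) {
  m_ctrl <- measure_epsc(average_aligned_sweeps(control, n),
                         n_sweeps_averaged = min(n, length(control$sweeps)))
  m_blk <- NULL
  br <- NA_real_
  if (!is.null(blocked)) {
    m_blk <- measure_epsc(average_aligned_sweeps(blocked, n),
                          n_sweeps_averaged = min(n, length(blocked$sweeps)))
    br <- block_ratio(m_ctrl, m_blk)
  }
  list(control = m_ctrl, blocked = m_blk, block_ratio = br)
}
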