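#' Construct a single sweep
#'
#' A sweep is one continuous trace recorded under a step or light-pulse
#' protocol: membrane potential (mV) in current clamp, membrane current (pA)
#' in voltage clamp. Time is measured in milliseconds from the first sample;
#' stimulus timing is carried as metadata, never inferred from the trace.
#'
#' @param samples Numeric vector of samples (mV or pA depending on `mode`).
#' @param sampling_rate Sampling rate in Hz. Default 10000 (10 kHz
#'   digitization, the convention assumed throughout).
#' @param stimulus_onset Stimulus onset, ms from sweep start.
#' @param stimulus_duration Stimulus duration, ms.
#' @param stimulus_amplitude Command amplitude in pA for current-clamp steps;
#'   for voltage-clamp light-pulse sweeps a marker value (e.g. 1).
#' @param mode `"current_clamp"` or `"voltage_clamp"`.
#' @return An object of class `fs_sweep`.
#' @seealso [fs_recording()], [baseline_window()]
#' @export
fs_sweep <- function(samples, sampling_rate = 10000, stimulus_onset = 0,
                     stimulus_duration = 0, stimulus_amplitude = 0,
                     mode = c("current_clamp", "voltage_clamp")) {
  mode <- match.arg(mode)
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) {
    stop("sweep samples must all be finite", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    stop("sampling_rate must be a single positive number (Hz)", call. = FALSE)
  }
  if (stimulus_onset < 0) {
    stop("stimulus_onset must be >= 0 ms", call. = FALSE)
  }
  dur_ms <- 1000 * length(samples) / sampling_rate
  if (stimulus_onset + stimulus_duration > dur_ms + 1e-9) {
    stop(sprintf(
      "stimulus window (%g + %g ms) exceeds sweep duration (%g ms)",
      stimulus_onset, stimulus_duration, dur_ms
    ), call. = FALSE)
  }
  structure(
    list(
      samples = samples,
      sampling_rate = sampling_rate,
      stimulus_onset = stimulus_onset,
      stimulus_duration = stimulus_duration,
      stimulus_amplitude = stimulus_amplitude,
      mode = mode
    ),
    class = "fs_sweep"
  )
}

#' Sample times of a sweep
#'
#' @param sweep An [fs_sweep()].
#' @return Numeric vector of times in ms, starting at 0.
#' @export
sweep_times <- function(sweep) {
  (seq_along(sweep$samples) - 1) * 1000 / sweep$sampling_rate
}

#' Sweep duration in ms
#' @param sweep An [fs_sweep()].
#' @return Duration in ms.
#' @export
sweep_duration <- function(sweep) {
  1000 * length(sweep$samples) / sweep$sampling_rate
}

#' @export
print.fs_sweep <- function(x, ...) {
  cat(sprintf(
    "<fs_sweep> %s, %d samples @ %g kHz (%.1f ms), stimulus %g pA [%g, %g] ms\n",
    x$mode, length(x$samples), x$sampling_rate / 1000, sweep_duration(x),
    x$stimulus_amplitude, x$stimulus_onset,
    x$stimulus_onset + x$stimulus_duration
  ))
  invisible(x)
}

#' Construct a recording
#'
#' A recording is an ordered collection of sweeps from one cell acquired
#' under a common mode and sampling rate (e.g. all steps of a current-step
#' protocol, or consecutive light-pulse trials).
#'
#' @param sweeps List of [fs_sweep()] objects sharing `mode` and
#'   `sampling_rate`.
#' @param cell_id Cell identifier string.
#' @param temperature Bath temperature, degrees C (default 32).
#' @param annotations Named list of free-form metadata strings.
#' @return An object of class `fs_recording`.
#' @export
fs_recording <- function(sweeps = list(), cell_id = "cell",
                         temperature = 32, annotations = list()) {
  if (!is.list(sweeps) || !all(vapply(sweeps, inherits, TRUE, "fs_sweep"))) {
    stop("sweeps must be a list of fs_sweep objects", call. = FALSE)
  }
  if (length(sweeps) > 0) {
    modes <- vapply(sweeps, `[[`, "", "mode")
    rates <- vapply(sweeps, `[[`, 0, "sampling_rate")
    if (length(unique(modes)) > 1L) {
      stop("all sweeps in a recording must share the same mode", call. = FALSE)
    }
    if (length(unique(rates)) > 1L) {
      stop("all sweeps in a recording must share the same sampling rate",
           call. = FALSE)
    }
  }
  structure(
    list(
      sweeps = sweeps,
      cell_id = as.character(cell_id),
      temperature = as.numeric(temperature),
      annotations = annotations
    ),
    class = "fs_recording"
  )
}

#' @export
print.fs_recording <- function(x, ...) {
  n <- length(x$sweeps)
  cat(sprintf("<fs_recording> cell '%s', %d sweep%s", x$cell_id, n,
              if (n == 1) "" else "s"))
  if (n > 0) {
    amps <- vapply(x$sweeps, `[[`, 0, "stimulus_amplitude")
    cat(sprintf(", %s @ %g kHz, steps %g..%g pA",
                x$sweeps[[1]]$mode, x$sweeps[[1]]$sampling_rate / 1000,
                min(amps), max(amps)))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.fs_recording <- function(x) length(x$sweeps)

#' Plot the sweeps of a recording
#'
#' Overlays all sweeps against time; a light grey band marks the stimulus
#' window of the first sweep.
#'
#' @param x An [fs_recording()].
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.fs_recording <- function(x, ...) {
  if (length(x$sweeps) == 0) stop("empty recording", call. = FALSE)
  t <- sweep_times(x$sweeps[[1]])
  v <- vapply(x$sweeps, `[[`, numeric(length(t)), "samples")
  ylab <- if (x$sweeps[[1]]$mode == "current_clamp") "V (mV)" else "I (pA)"
  graphics::matplot(t, v, type = "l", lty = 1, xlab = "time (ms)",
                    ylab = ylab, ...)
  s <- x$sweeps[[1]]
  graphics::abline(v = c(s$stimulus_onset, s$stimulus_onset + s$stimulus_duration),
                   col = "grey70", lty = 3)
  invisible(x)
}

#' Pre-stimulus baseline mean and standard deviation
#'
#' Summarizes the window of given length ending at the stimulus onset.
#' Used for the resting potential, deflection references and EPSC baselines.
#'
#' @param sweep An [fs_sweep()].
#' @param length Window length in ms; must be positive and no longer than the
#'   pre-stimulus segment.
#' @return Named list with `mean` and `sd` in the sweep's units.
#' @export
baseline_window <- function(sweep, length) {
  stopifnot(inherits(sweep, "fs_sweep"))
  if (!is.numeric(length) || length <= 0) {
    stop("baseline window length must be positive", call. = FALSE)
  }
  if (length > sweep$stimulus_onset + 1e-9) {
    stop(sprintf(
      "baseline window (%g ms) exceeds pre-stimulus segment (%g ms)",
      length, sweep$stimulus_onset
    ), call. = FALSE)
  }
  t <- sweep_times(sweep)
  idx <- which(t >= sweep$stimulus_onset - length & t < sweep$stimulus_onset)
  x <- sweep$samples[idx]
  list(mean = mean(x), sd = stats::sd(x))
}

# Internal: indices of the stimulus window, and of its final `frac` tail.
stim_indices <- function(sweep, frac = NULL) {
  t <- sweep_times(sweep)
  on <- sweep$stimulus_onset
  off <- on + sweep$stimulus_duration
  if (is.null(frac)) {
    which(t >= on & t < off)
  } else {
    which(t >= off - frac * sweep$stimulus_duration & t < off)
  }
}

# Internal: step sweeps at a given command amplitude (numeric tolerance).
sweeps_at <- function(rec, amplitude, tol = 1e-6) {
  amps <- vapply(rec$sweeps, `[[`, 0, "stimulus_amplitude")
  rec$sweeps[abs(amps - amplitude) < tol]
}
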