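#' Write a recording to a delimited text file
#'
#' The on-disk format is plain tab-delimited text: `#`-prefixed
#' `key=value` header lines followed by one column per sweep and one row per
#' sample. Values are written with 17 significant digits, so a write/read
#' cycle reproduces every sample bit-for-bit. The format is intentionally
#' diff-able and language-agnostic.
#'
#' Header keys: `mode`, `sampling_rate_hz`, `units`, `n_sweeps`,
#' `stimulus_onset_ms`, `stimulus_duration_ms`, `stimulus_amplitude_pa`
#' (the three stimulus fields are comma-separated lists, one entry per sweep,
#' or a single value shared by all sweeps), `cell_id`, `temperature_c`, and
#' free-form `annotation:<key>` lines.
#'
#' @param rec An [fs_recording()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @seealso [read_recording()]
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "fs_recording"))
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop(sprintf("cannot open '%s' for writing: %s", path,
                 conditionMessage(e)), call. = FALSE)
  })
  on.exit(close(con))
  n <- length(rec$sweeps)
  mode <- if (n > 0) rec$sweeps[[1]]$mode else "current_clamp"
  units <- if (mode == "current_clamp") "mV" else "pA"
  num <- function(x) formatC(x, digits = 17, format = "g")
  csv <- function(field) paste(vapply(rec$sweeps, function(s) num(s[[field]]),
                                      ""), collapse = ",")
  writeLines(c(
    "# fastspike_sweeps v1",
    paste0("# mode=", mode),
    paste0("# sampling_rate_hz=",
           num(if (n > 0) rec$sweeps[[1]]$sampling_rate else 10000)),
    paste0("# units=", units),
    paste0("# n_sweeps=", n),
    paste0("# stimulus_onset_ms=", csv("stimulus_onset")),
    paste0("# stimulus_duration_ms=", csv("stimulus_duration")),
    paste0("# stimulus_amplitude_pa=", csv("stimulus_amplitude")),
    paste0("# cell_id=", rec$cell_id),
    paste0("# temperature_c=", num(rec$temperature))
  ), con)
  if (length(rec$annotations) > 0) {
    writeLines(sprintf("# annotation:%s=%s", names(rec$annotations),
                       vapply(rec$annotations, as.character, "")), con)
  }
  if (n > 0) {
    m <- vapply(rec$sweeps, `[[`, numeric(length(rec$sweeps[[1]]$samples)),
                "samples")
    m <- matrix(m, ncol = n)
    utils::write.table(matrix(num(m), ncol = n), con, sep = "\t",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a recording from a delimited text file
#'
#' Reads the format written by [write_recording()]. Units are normalized on
#' input: voltages stored in V are converted to mV, currents in nA to pA, so
#' downstream code always sees mV/pA/ms regardless of the declared unit.
#' Normalization is idempotent (a file already in mV/pA is returned as-is).
#'
#' @param path Input file path.
#' @return An [fs_recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  }
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  if (length(hdr_idx) == 0 || any(diff(hdr_idx) != 1) || hdr_idx[1] != 1L) {
    stop("malformed file: header must be a leading block of '#' lines",
         call. = FALSE)
  }
  hdr <- list()
  for (i in hdr_idx[-1]) {             # first line is the format tag
    line <- sub("^#\\s*", "", lines[i])
    if (!grepl("=", line, fixed = TRUE)) {
      stop(sprintf("malformed header line %d: '%s' (expected key=value)",
                   i, lines[i]), call. = FALSE)
    }
    key <- sub("=.*$", "", line)
    hdr[[key]] <- sub("^[^=]*=", "", line)
  }
  need <- function(key) {
    if (is.null(hdr[[key]])) {
      stop(sprintf("malformed header: missing required key '%s'", key),
           call. = FALSE)
    }
    hdr[[key]]
  }
  mode <- need("mode")
  if (!mode %in% c("current_clamp", "voltage_clamp")) {
    stop(sprintf("invalid mode '%s' (mixed or unknown modes not supported)",
                 mode), call. = FALSE)
  }
  rate <- as.numeric(need("sampling_rate_hz"))
  if (!is.finite(rate) || rate <= 0) {
    stop("malformed header: sampling_rate_hz must be a positive number",
         call. = FALSE)
  }
  units <- need("units")
  scale <- switch(units,
    mV = 1, pA = 1, V = 1000, nA = 1000,
    stop(sprintf("unsupported units '%s'", units), call. = FALSE)
  )
  if (mode == "current_clamp" && !units %in% c("mV", "V")) {
    stop("current-clamp files must store voltages (mV or V)", call. = FALSE)
  }
  if (mode == "voltage_clamp" && !units %in% c("pA", "nA")) {
    stop("voltage-clamp files must store currents (pA or nA)", call. = FALSE)
  }
  n <- as.integer(need("n_sweeps"))
  numlist <- function(key) {
    v <- as.numeric(strsplit(need(key), ",", fixed = TRUE)[[1]])
    if (length(v) == 1L) v <- rep(v, n)
    if (n > 0 && length(v) != n) {
      stop(sprintf("header key '%s' has %d entries for %d sweeps",
                   key, length(v), n), call. = FALSE)
    }
    v
  }
  onset <- numlist("stimulus_onset_ms")
  dur <- numlist("stimulus_duration_ms")
  amp <- numlist("stimulus_amplitude_pa")
  ann_keys <- grep("^annotation:", names(hdr), value = TRUE)
  annotations <- stats::setNames(hdr[ann_keys],
                                 sub("^annotation:", "", ann_keys))
  sweeps <- list()
  if (n > 0) {
    body <- lines[-hdr_idx]
    body <- body[nzchar(body)]
    m <- matrix(as.numeric(unlist(strsplit(body, "\t", fixed = TRUE))),
                ncol = n, byrow = TRUE)
    if (any(!is.finite(m))) {
      stop("malformed file: non-numeric or non-finite sample values",
           call. = FALSE)
    }
    sweeps <- lapply(seq_len(n), function(j) {
      fs_sweep(m[, j] * scale, sampling_rate = rate, stimulus_onset = onset[j],
               stimulus_duration = dur[j], stimulus_amplitude = amp[j],
               mode = mode)
    })
  }
  fs_recording(sweeps,
               cell_id = if (is.null(hdr$cell_id)) "cell" else hdr$cell_id,
               temperature = if (is.null(hdr$temperature_c)) NA_real_
                             else as.numeric(hdr$temperature_c),
               annotations = annotations)
}
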