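#' Collapse technical replicates with the limit-of-detection rule
#'
#' Replicates with Ct above the limit of detection (`lod_ct`, strictly: a Ct
#' of exactly 37.0 survives a limit of 37) and wells lacking any
#' amplification curve (missing Ct) are dropped. When no replicate survives,
#' the (cell, gene) entry is censored; otherwise its Ct is the arithmetic
#' mean of the surviving replicates.
#'
#' @param plate An `fs_qpcr_plate` (see [qpcr_plate()], [read_qpcr_plate()],
#'   [simulate_qpcr_plate()]).
#' @param lod_ct Override for the plate's limit of detection, cycles.
#' @return Data frame with one row per (cell_id, gene): `ct` (mean Ct, NA
#'   when censored), `n_replicates` (surviving count), `censored`.
#' @export
collapse_replicates <- function(plate, lod_ct = NULL) {
  stopifnot(inherits(plate, "fs_qpcr_plate"))
  if (is.null(lod_ct)) lod_ct <- attr(plate, "lod_ct")
  d <- as.data.frame(plate)
  keys <- unique(d[, c("cell_id", "gene")])
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sel <- d$cell_id == keys$cell_id[i] & d$gene == keys$gene[i]
    ct <- d$ct[sel]
    ok <- !is.na(ct) & ct <= lod_ct
    data.frame(cell_id = keys$cell_id[i], gene = keys$gene[i],
               ct = if (any(ok)) mean(ct[ok]) else NA_real_,
               n_replicates = sum(ok), censored = !any(ok),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' Per cell, `dCt = Ct_target - mean(Ct over reference genes)`. The ddCt
#' subtracts a calibrator dCt and the reported value is `2^-ddCt`:
#'
#' * `calibrator = "cohort"` (default): the cohort-mean dCt of each target
#'   gene, making values fold-changes relative to the cohort average of that
#'   gene (each gene's values then center on 1).
#' * `calibrator = "none"`: no subtraction, i.e. plain `2^-dCt` expression
#'   relative to the reference genes; this preserves abundance ratios
#'   *between* genes and is what cross-gene comparisons and recovery checks
#'   use.
#' * a cell id: that cell (e.g. a designated positive-control sample) is the
#'   calibrator for every gene.
#'
#' Cells with a censored reference gene are excluded with a warning; cells
#' with a censored target get a censored output for that gene.
#'
#' @param cts Collapsed Ct table from [collapse_replicates()].
#' @param targets Character vector of target genes.
#' @param references Character vector of reference genes.
#' @param calibrator `"cohort"`, `"none"`, or a cell id present in `cts`.
#' @return An object of class `fs_rel_abundance`: data frame with
#'   `cell_id`, `gene`, `delta_ct`, `value` (NA when censored), `censored`;
#'   attributes `reference_genes` and `calibrator`.
#' @export
relative_abundance <- function(cts, targets, references,
                               calibrator = "cohort") {
  stopifnot(is.data.frame(cts),
            all(c("cell_id", "gene", "ct", "censored") %in% names(cts)))
  missing_ref <- setdiff(references, cts$gene)
  if (length(missing_ref) > 0) {
    stop(sprintf("reference gene(s) absent from table: %s",
                 paste(missing_ref, collapse = ", ")), call. = FALSE)
  }
  cells <- unique(cts$cell_id)
  ref_ct <- vapply(cells, function(cell) {
    r <- cts[cts$cell_id == cell & cts$gene %in% references, ]
    if (any(r$censored) || nrow(r) < length(references)) NA_real_
    else mean(r$ct)
  }, 0)
  bad <- cells[is.na(ref_ct)]
  if (length(bad) > 0) {
    warning(sprintf("excluding cell(s) with censored reference genes: %s",
                    paste(bad, collapse = ", ")))
    cells <- setdiff(cells, bad)
  }
  if (length(cells) == 0) stop("no cell has all reference genes detected",
                               call. = FALSE)
  out <- do.call(rbind, lapply(targets, function(g) {
    rows <- do.call(rbind, lapply(cells, function(cell) {
      r <- cts[cts$cell_id == cell & cts$gene == g, ]
      dct <- if (nrow(r) == 1 && !r$censored) r$ct - ref_ct[[cell]]
             else NA_real_
      data.frame(cell_id = cell, gene = g, delta_ct = dct,
                 stringsAsFactors = FALSE)
    }))
    cal <- if (identical(calibrator, "cohort")) {
      mean(rows$delta_ct, na.rm = TRUE)
    } else if (identical(calibrator, "none")) {
      0
    } else {
      cal_dct <- rows$delta_ct[rows$cell_id == calibrator]
      if (length(cal_dct) != 1 || is.na(cal_dct)) {
        stop(sprintf(
          "calibrator cell '%s' has no usable dCt for gene '%s'",
          calibrator, g), call. = FALSE)
      }
      cal_dct
    }
    rows$value <- 2^-(rows$delta_ct - cal)
    rows$censored <- is.na(rows$delta_ct)
    rows
  }))
  rownames(out) <- NULL
  structure(out, reference_genes = references, calibrator = calibrator,
            class = c("fs_rel_abundance", "data.frame"))
}

#' Summarize relative abundance per gene
#'
#' Per-gene mean, median, quartiles and s.e.m. of the uncensored values,
#' with `n` reflecting exclusions. Genes with no uncensored value are
#' omitted with a warning; a single-value gene gets a missing s.e.m.
#'
#' @param ra An [relative_abundance()] result.
#' @return Data frame with `gene`, `n`, `mean`, `median`, `q1`, `q3`, `sem`.
#' @export
summarize_abundance <- function(ra) {
  stopifnot(inherits(ra, "fs_rel_abundance"))
  out <- do.call(rbind, lapply(unique(ra$gene), function(g) {
    x <- ra$value[ra$gene == g & !ra$censored]
    if (length(x) == 0) {
      warning(sprintf("gene '%s' has no uncensored values; omitted", g))
      return(NULL)
    }
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(gene = g, n = length(x), mean = mean(x), median = q[2],
               q1 = q[1], q3 = q[3],
               sem = if (length(x) > 1) stats::sd(x) / sqrt(length(x))
                     else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) stop("all genes fully censored", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' @export
print.fs_rel_abundance <- function(x, ...) {
  cat(sprintf(
    "Relative abundance (2^-ddCt, references: %s; calibrator: %s)\n",
    paste(attr(x, "reference_genes"), collapse = "+"),
    attr(x, "calibrator")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' One-call qPCR pipeline
#'
#' [collapse_replicates()] then [relative_abundance()].
#'
#' @inheritParams collapse_replicates
#' @inheritParams relative_abundance
#' @return An `fs_rel_abundance`.
#' @export
qpcr_pipeline <- function(plate, targets, references,
                          calibrator = "cohort", lod_ct = NULL) {
  relative_abundance(collapse_replicates(plate, lod_ct = lod_ct),
                     targets, references, calibrator = calibrator)
}
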