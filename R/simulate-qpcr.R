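#' Parameters for the single-cell qPCR plate generator
#'
#' Emulates triplicate TaqMan Ct measurements from harvested single-cell
#' cytoplasm. The default gene panel and conditions follow the study design:
#' Pvalb and Vglut2 as reference genes, Kv3.1, Kv3.2 and Hcn2 as targets with
#' comparable abundance, Vgat essentially absent (its expected Ct falls
#' beyond the detection limit of 37 cycles), eight cells, triplicates.
#'
#' @param genes Character vector of gene names.
#' @param true_relative_abundance Positive per-gene expression levels (named
#'   like `genes` or in the same order). A gene with abundance `x` has
#'   expected Ct `base_ct - log2(x)`.
#' @param reference_genes Subset of `genes` used for normalization.
#' @param replicate_sd Technical replicate noise, Ct cycles.
#' @param dropout_prob Probability that a replicate yields no amplification
#'   curve (missing Ct). Scalar or per-gene vector.
#' @param lod_ct Limit of detection, cycles (default 37): Ct above this is
#'   below the limit of detection downstream.
#' @param n_cells Number of cells on the plate.
#' @param base_ct Ct of a gene with abundance 1 (default 30).
#' @return An object of class `fs_qpcr_sim_params`.
#' @export
qpcr_sim_params <- function(genes = c("Pvalb", "Vglut2", "Vgat", "Kv3.1",
                                      "Kv3.2", "Hcn2"),
                            true_relative_abundance = c(Pvalb = 4,
                                                        Vglut2 = 4,
                                                        Vgat = 0.002,
                                                        Kv3.1 = 1,
                                                        Kv3.2 = 0.8,
                                                        Hcn2 = 1.2),
                            reference_genes = c("Pvalb", "Vglut2"),
                            replicate_sd = 0.3, dropout_prob = 0,
                            lod_ct = 37, n_cells = 8, base_ct = 30) {
  genes <- as.character(genes)
  if (is.null(names(true_relative_abundance))) {
    names(true_relative_abundance) <- genes
  }
  if (!all(genes %in% names(true_relative_abundance))) {
    stop("true_relative_abundance must cover every gene", call. = FALSE)
  }
  if (any(true_relative_abundance <= 0)) {
    stop("abundances must be positive", call. = FALSE)
  }
  if (!all(reference_genes %in% genes)) {
    stop("reference_genes must be a subset of genes", call. = FALSE)
  }
  if (length(dropout_prob) == 1L) {
    dropout_prob <- stats::setNames(rep(dropout_prob, length(genes)), genes)
  }
  if (any(dropout_prob < 0 | dropout_prob > 1)) {
    stop("dropout_prob must be in [0, 1]", call. = FALSE)
  }
  structure(list(genes = genes,
                 true_relative_abundance = true_relative_abundance[genes],
                 reference_genes = reference_genes,
                 replicate_sd = replicate_sd, dropout_prob = dropout_prob,
                 lod_ct = lod_ct, n_cells = as.integer(n_cells),
                 base_ct = base_ct),
            class = "fs_qpcr_sim_params")
}

#' Simulate a triplicate single-cell qPCR plate
#'
#' Draws `Ct = base_ct - log2(abundance) + N(0, replicate_sd)` per replicate,
#' with per-replicate dropouts emitted as missing. Values above the limit of
#' detection are retained in the table (censoring is applied downstream by
#' [collapse_replicates()]), matching how an instrument reports them.
#'
#' @param params A [qpcr_sim_params()] object.
#' @param seed Integer seed; the plate is bit-reproducible given
#'   `(params, seed)`.
#' @return An object of class `fs_qpcr_plate`: a data frame with columns
#'   `cell_id`, `gene`, `replicate`, `ct` (NA = no amplification) and an
#'   `lod_ct` attribute.
#' @export
simulate_qpcr_plate <- function(params, seed = 1) {
  stopifnot(inherits(params, "fs_qpcr_sim_params"))
  with_local_seed(seed, {
    grid <- expand.grid(replicate = 1:3, gene = params$genes,
                        cell_id = sprintf("cell%02d", seq_len(params$n_cells)),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid <- grid[, c("cell_id", "gene", "replicate")]
    mu <- params$base_ct - log2(params$true_relative_abundance[grid$gene])
    ct <- mu + stats::rnorm(nrow(grid), 0, params$replicate_sd)
    drop <- stats::runif(nrow(grid)) < params$dropout_prob[grid$gene]
    ct[drop] <- NA_real_
    qpcr_plate(grid$cell_id, grid$gene, grid$replicate, ct,
               lod_ct = params$lod_ct)
  })
}

#' Construct a qPCR plate table
#'
#' @param cell_id,gene,replicate,ct Parallel vectors, one entry per
#'   well/replicate; `ct` is the cycle threshold (NA when no amplification
#'   curve was observed).
#' @param lod_ct Limit of detection in cycles (default 37).
#' @return An `fs_qpcr_plate` data frame.
#' @export
qpcr_plate <- function(cell_id, gene, replicate, ct, lod_ct = 37) {
  replicate <- as.integer(replicate)
  if (!all(replicate %in% 1:3)) {
    stop("replicate index must be 1, 2 or 3", call. = FALSE)
  }
  ct <- as.numeric(ct)
  if (any(!is.na(ct) & ct <= 0)) {
    stop("Ct values must be positive", call. = FALSE)
  }
  structure(
    data.frame(cell_id = as.character(cell_id), gene = as.character(gene),
               replicate = replicate, ct = ct, stringsAsFactors = FALSE),
    lod_ct = lod_ct,
    class = c("fs_qpcr_plate", "data.frame")
  )
}

#' Read a qPCR plate from delimited text
#'
#' Expects a tab- or comma-delimited table with header columns `cell_id`,
#' `gene`, `replicate`, `ct`; empty `ct` fields are missing wells.
#'
#' @param path Input file path.
#' @param lod_ct Limit of detection in cycles (default 37).
#' @return An `fs_qpcr_plate`.
#' @export
read_qpcr_plate <- function(path, lod_ct = 37) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path),
                               call. = FALSE)
  sep <- if (grepl(",", readLines(path, n = 1))) "," else "\t"
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  need <- c("cell_id", "gene", "replicate", "ct")
  if (!all(need %in% names(d))) {
    stop(sprintf("qPCR table must have columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  qpcr_plate(d$cell_id, d$gene, d$replicate, d$ct, lod_ct = lod_ct)
}
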