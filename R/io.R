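# Plain-text readers/writers for the pipeline's external formats: TSV
# expression matrices (rows = probes, first column = probe id), probe and
# cell annotation TSVs, qPCR Ct TSVs (40 = undetected), ground-truth JSON.

#' Write a simulated dataset to a directory of TSV/JSON files
#'
#' Files: `matrix.tsv` (probes x cells linear signals), `probes.tsv`
#' (probe_id, class, spike_copies), `cells.tsv` (cell_id, stage, type,
#' condition), `truth.json` (latent coordinates and gene effects).
#'
#' @param dataset list with `matrix` and `truth`, as from
#'   [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  se <- dataset$matrix
  truth <- dataset$truth
  write_matrix_tsv(signal_matrix(se), file.path(dir, "matrix.tsv"),
                   id_col = "probe_id")
  rd <- as.data.frame(SummarizedExperiment::rowData(se))
  utils::write.table(
    data.frame(probe_id = rownames(rd), class = rd$class,
               spike_copies = rd$spike_copies),
    file.path(dir, "probes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    truth$cells[, c("cell_id", "stage", "type", "condition")],
    file.path(dir, "cells.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(
    list(cells = truth$cells, genes = truth$genes,
         frozen_genes = truth$frozen_genes),
    file.path(dir, "truth.json"), dataframe = "columns", digits = NA)
  invisible(dir)
}

write_matrix_tsv <- function(m, path, id_col = "probe_id") {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read an expression matrix (and annotations) from TSV
#'
#' @param matrix_tsv path to a probes x cells TSV whose first column is the
#'   probe id.
#' @param probes_tsv,cells_tsv optional annotation TSVs (first columns
#'   `probe_id` / `cell_id`).
#' @return A `SummarizedExperiment` with assay `signal`.
#' @export
read_expression_tsv <- function(matrix_tsv, probes_tsv = NULL,
                                cells_tsv = NULL) {
  df <- utils::read.delim(matrix_tsv, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  rd <- if (!is.null(probes_tsv)) {
    p <- utils::read.delim(probes_tsv)
    S4Vectors::DataFrame(p[match(rownames(m), p[[1L]]), -1L, drop = FALSE],
                         row.names = rownames(m))
  } else S4Vectors::DataFrame(row.names = rownames(m))
  cd <- if (!is.null(cells_tsv)) {
    cc <- utils::read.delim(cells_tsv)
    S4Vectors::DataFrame(cc[match(colnames(m), cc[[1L]]), -1L, drop = FALSE],
                         row.names = colnames(m))
  } else S4Vectors::DataFrame(row.names = colnames(m))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(signal = m), rowData = rd, colData = cd)
}

#' Write a qPCR Ct table as TSV (40 = undetected)
#' @param q a [qpcr_table()].
#' @param path output file.
#' @export
write_qpcr_tsv <- function(q, path) {
  stopifnot(inherits(q, "qpcr_table"))
  write_matrix_tsv(q$ct, path, id_col = "gene_id")
  invisible(path)
}

#' Read a qPCR Ct table from TSV
#' @param path TSV with gene-id first column; Ct values, 40 = undetected.
#' @return A [qpcr_table()].
#' @export
read_qpcr_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  qpcr_table(m)
}
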