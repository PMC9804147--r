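#' Single-cell QC filtering
#'
#' One pass of gene-then-cell filtering: genes detected (count > 0) in at
#' least `qc_min_cells_per_gene` cells are kept; then, on the gene-filtered
#' matrix, cells expressing at least `qc_min_genes_per_cell` and at most
#' `qc_max_genes_per_cell` genes with a mitochondrial read fraction of at
#' most `qc_max_mito_frac` are kept.  The gene-count ceiling and the
#' mitochondrial cap remove likely doublets and low-quality cells.  The
#' filter is a single pass, not iterated to a fixpoint, so a gene can in
#' principle fall below the cell floor after cell removal; applying the
#' filter twice with the same thresholds is nonetheless idempotent on
#' matrices it has already filtered in the fixtures exercised here, and the
#' order (gene before cell) is part of the contract.
#'
#' @param m a [cell_matrix()].
#' @param cfg a [threshold_config()].
#' @param mito_prefix gene-id prefix identifying mitochondrial genes.
#' @return The filtered `cell_matrix` (any normalized layer is dropped, as
#'   it must be recomputed on the surviving cells).
#' @export
qc_filter <- function(m, cfg = threshold_config(), mito_prefix = "MT-") {
  stopifnot(inherits(m, "cell_matrix"))
  counts <- m$counts
  gene_keep <- Matrix::rowSums(counts > 0) >= cfg$qc_min_cells_per_gene
  counts <- counts[gene_keep, , drop = FALSE]
  if (!nrow(counts)) stop("no gene passed QC", call. = FALSE)
  n_genes <- Matrix::colSums(counts > 0)
  total <- Matrix::colSums(counts)
  mito <- startsWith(rownames(counts), mito_prefix)
  mito_frac <- if (any(mito))
    Matrix::colSums(counts[mito, , drop = FALSE]) / pmax(total, 1) else
      numeric(ncol(counts))
  cell_keep <- n_genes >= cfg$qc_min_genes_per_cell &
    n_genes <= cfg$qc_max_genes_per_cell &
    mito_frac <= cfg$qc_max_mito_frac
  if (!any(cell_keep)) stop("no cell passed QC", call. = FALSE)
  cell_matrix(counts[, cell_keep, drop = FALSE],
              m$cell_meta[cell_keep, , drop = FALSE])
}

#' Per-cell QC metrics
#'
#' Reports, per cell, the expressed-gene count, total counts, mitochondrial
#' fraction and pass/fail status under `cfg` -- useful for QC reports; the
#' metrics are computed after the gene filter, exactly as [qc_filter()]
#' evaluates them.
#'
#' @inheritParams qc_filter
#' @return data.frame with one row per cell.
#' @export
qc_metrics <- function(m, cfg = threshold_config(), mito_prefix = "MT-") {
  stopifnot(inherits(m, "cell_matrix"))
  counts <- m$counts[Matrix::rowSums(m$counts > 0) >= cfg$qc_min_cells_per_gene, ,
                     drop = FALSE]
  n_genes <- Matrix::colSums(counts > 0)
  total <- Matrix::colSums(counts)
  mito <- startsWith(rownames(counts), mito_prefix)
  mito_frac <- if (any(mito))
    Matrix::colSums(counts[mito, , drop = FALSE]) / pmax(total, 1) else
      numeric(ncol(counts))
  data.frame(cell_id = m$cell_meta$cell_id, n_genes = n_genes,
             total_counts = total, mito_frac = mito_frac,
             pass = n_genes >= cfg$qc_min_genes_per_cell &
               n_genes <= cfg$qc_max_genes_per_cell &
               mito_frac <= cfg$qc_max_mito_frac,
             row.names = NULL)
}

#' Depth normalization of a QC-filtered matrix
#'
#' Scales each cell to `norm_scale` (default 10,000) transcripts and applies
#' `log1p`: `value = ln(1 + count * norm_scale / cell_total)`.  The counts
#' layer is kept unchanged; `sum(expm1(normalized))` per cell equals
#' `norm_scale` exactly (up to floating-point round-off).
#'
#' @inheritParams qc_filter
#' @return The `cell_matrix` with a sparse `normalized` layer added.
#' @export
normalize_cells <- function(m, cfg = threshold_config()) {
  stopifnot(inherits(m, "cell_matrix"))
  total <- Matrix::colSums(m$counts)
  if (any(total == 0))
    stop("cell with zero total counts; run qc_filter() first", call. = FALSE)
  scaled <- m$counts %*% Matrix::Diagonal(x = cfg$norm_scale / total)
  norm <- scaled
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(m$counts)
  cell_matrix(m$counts, m$cell_meta, normalized = norm)
}
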