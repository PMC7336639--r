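#' Quality-control parameters
#'
#' Cells are retained with strictly more than `min_umi` UMIs and strictly
#' less than `max_mito_frac` of UMIs on mitochondrial genes; genes are
#' then retained if expressed in at least `min_cells_per_gene` of the
#' retained cells.
#'
#' @param min_umi minimum UMI count per cell (strict, default 1000).
#' @param max_mito_frac maximum mitochondrial UMI fraction per cell
#'   (strict, default 0.20).
#' @param min_cells_per_gene minimum expressing cells per gene
#'   (non-strict, default 3).
#' @param mito_prefix gene-symbol prefix identifying mitochondrial genes.
#' @return list of class `qc_params`.
#' @export
qc_params <- function(min_umi = 1000, max_mito_frac = 0.20,
                      min_cells_per_gene = 3, mito_prefix = "MT-") {
  if (max_mito_frac < 0 || max_mito_frac > 1)
    stop("max_mito_frac must be in [0, 1]")
  if (min_umi < 0 || min_cells_per_gene < 0)
    stop("QC thresholds must be >= 0")
  structure(list(min_umi = min_umi, max_mito_frac = max_mito_frac,
                 min_cells_per_gene = min_cells_per_gene,
                 mito_prefix = mito_prefix),
            class = "qc_params")
}

#' Per-cell quality-control statistics
#'
#' Computes, for every cell, its total UMI count, the number of genes
#' detected (count > 0) and the percentage of UMIs mapped to
#' mitochondrial genes (symbols starting with `mito_prefix`). An all-zero
#' cell has `pct_mito` 0.
#'
#' @param m genes x cells count matrix.
#' @param params a [qc_params()].
#' @return data.frame with columns `barcode`, `n_umi`, `n_genes_detected`,
#'   `pct_mito`.
#' @export
compute_cell_qc <- function(m, params = qc_params()) {
  if (nrow(m) == 0) stop("count matrix has no genes")
  n_umi <- Matrix::colSums(m)
  n_genes <- Matrix::colSums(m > 0)
  mito <- startsWith(rownames(m), params$mito_prefix)
  mito_umi <- if (any(mito)) Matrix::colSums(m[mito, , drop = FALSE]) else
    numeric(ncol(m))
  pct_mito <- ifelse(n_umi > 0, 100 * mito_umi / n_umi, 0)
  data.frame(barcode = colnames(m), n_umi = as.numeric(n_umi),
             n_genes_detected = as.integer(n_genes),
             pct_mito = as.numeric(pct_mito),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Apply cell and gene quality-control filters
#'
#' Cell filtering precedes gene filtering: cells failing the UMI or
#' mitochondrial rule are dropped first, then gene detection is counted
#' over the surviving cells only. Row and column order is preserved.
#'
#' @param m genes x cells count matrix.
#' @param qc per-cell statistics from [compute_cell_qc()], aligned to `m`.
#' @param params a [qc_params()].
#' @return The filtered count matrix.
#' @export
apply_qc_filters <- function(m, qc, params = qc_params()) {
  if (!identical(as.character(qc$barcode), as.character(colnames(m))))
    stop("QC table is not aligned to the count matrix columns")
  keep_cells <- qc$n_umi > params$min_umi &
    qc$pct_mito < 100 * params$max_mito_frac
  m <- m[, keep_cells, drop = FALSE]
  n_expressing <- Matrix::rowSums(m > 0)
  m[n_expressing >= params$min_cells_per_gene, , drop = FALSE]
}
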