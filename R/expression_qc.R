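#' Single-cell QC and normalization
#'
#' Applies the cell and gene filters and the library-size normalization to a
#' raw UMI count matrix:
#' * cells with more than 5% of their UMIs in mitochondrial genes are
#'   excluded (strictly more; exactly 5% is retained);
#' * genes are kept only if they have at least `min_umi` UMIs in at least
#'   `min_cell_frac` of the retained cells;
#' * expression of gene i in cell j is `log2(10000 * umi_ij / total_j + 1)`,
#'   where `total_j` sums over all genes (before gene filtering), so the
#'   pre-log values of a cell sum to 10,000.
#'
#' @param counts genes x cells matrix of raw UMI counts (dense or
#'   `Matrix::sparseMatrix`); rownames are gene ids, colnames cell barcodes.
#' @param mito_genes character vector of mitochondrial gene ids; by default
#'   genes whose symbol starts with `"mt-"` (case-insensitive).
#' @param max_mito_fraction cells above this mitochondrial UMI fraction are
#'   excluded (default 0.05, strict).
#' @param min_umi,min_cell_frac gene-filter parameters (defaults 3 UMIs and
#'   5% of retained cells, both inclusive).
#' @return object of class `expr_qc`: list with `counts` (raw, as given),
#'   `logcounts` (dense genes x cells matrix, retained genes x retained cells),
#'   `cell_mask`, `gene_mask` (named logicals over all input cells/genes) and
#'   `mito_fraction` (per input cell).
#' @export
qc_expression <- function(counts, mito_genes = NULL,
                          max_mito_fraction = 0.05,
                          min_umi = 3, min_cell_frac = 0.05) {
  if (!nrow(counts) || !ncol(counts)) stop("empty count matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene rownames and cell colnames")
  }
  cm <- filter_cells(counts, mito_genes, max_mito_fraction)
  gm <- filter_genes(counts, cm$cell_mask, min_umi, min_cell_frac)
  logc <- normalize_expression(counts, cm$cell_mask, gm)
  structure(list(
    counts = counts,
    logcounts = logc,
    cell_mask = cm$cell_mask,
    gene_mask = gm,
    mito_fraction = cm$mito_fraction
  ), class = "expr_qc")
}

#' Mitochondrial-content cell filter
#'
#' @inheritParams qc_expression
#' @return list with `cell_mask` (TRUE = retained) and `mito_fraction`.
#' @export
filter_cells <- function(counts, mito_genes = NULL, max_mito_fraction = 0.05) {
  if (!nrow(counts) || !ncol(counts)) stop("empty count matrix")
  if (is.null(mito_genes)) {
    mito_genes <- grep("^mt-", rownames(counts), ignore.case = TRUE, value = TRUE)
  } else {
    missing <- setdiff(mito_genes, rownames(counts))
    if (length(missing)) {
      stop("mito genes not in matrix: ", paste(missing, collapse = ", "))
    }
  }
  totals <- Matrix::colSums(counts)
  mito <- if (length(mito_genes)) {
    Matrix::colSums(counts[mito_genes, , drop = FALSE])
  } else {
    numeric(ncol(counts))
  }
  frac <- ifelse(totals > 0, mito / totals, 0)
  mask <- frac <= max_mito_fraction & totals > 0
  names(mask) <- colnames(counts)
  names(frac) <- colnames(counts)
  list(cell_mask = mask, mito_fraction = frac)
}

#' Detection-based gene filter
#'
#' A gene is retained iff it has at least `min_umi` UMIs in at least
#' `min_cell_frac` of the retained cells (both thresholds inclusive).
#'
#' @inheritParams qc_expression
#' @param cell_mask logical over cells, TRUE = retained (from
#'   [filter_cells()]).
#' @return named logical over genes.
#' @export
filter_genes <- function(counts, cell_mask, min_umi = 3, min_cell_frac = 0.05) {
  sub <- counts[, cell_mask, drop = FALSE]
  n_cells <- ncol(sub)
  n_detect <- Matrix::rowSums(sub >= min_umi)
  mask <- n_detect >= min_cell_frac * n_cells
  names(mask) <- rownames(counts)
  mask
}

#' Library-size normalization to log2(TPM-like + 1)
#'
#' @inheritParams qc_expression
#' @param cell_mask,gene_mask logical masks; defaults keep everything.
#' @param scale scale factor applied to per-cell fractions (default 10,000).
#' @return dense matrix (retained genes x retained cells) of
#'   `log2(scale * umi/total + 1)` values; cell totals are computed over all
#'   genes, before gene filtering.
#' @export
normalize_expression <- function(counts,
                                 cell_mask = rep(TRUE, ncol(counts)),
                                 gene_mask = rep(TRUE, nrow(counts)),
                                 scale = 1e4) {
  totals <- Matrix::colSums(counts)[cell_mask]
  if (any(totals <= 0)) {
    stop("cells with zero total UMIs must be filtered before normalization")
  }
  sub <- counts[gene_mask, cell_mask, drop = FALSE]
  tpm <- sweep(as.matrix(sub), 2, totals, "/") * scale
  log2(tpm + 1)
}

#' @export
print.expr_qc <- function(x, ...) {
  cat("QC'd expression matrix\n")
  cat(sprintf("  cells: %d of %d retained (mito fraction filter)\n",
              sum(x$cell_mask), length(x$cell_mask)))
  cat(sprintf("  genes: %d of %d retained (detection filter)\n",
              sum(x$gene_mask), length(x$gene_mask)))
  invisible(x)
}
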