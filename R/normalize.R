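#' Scale-factor log-normalization of raw counts
#'
#' Standard single-cell log-normalization: each count is divided by its
#' cell's total count, multiplied by a fixed scale factor, and
#' log-transformed with a pseudocount of one,
#' `log(1 + count * scale.factor / cell_total)` (natural log). Zeros map
#' to zeros, so the sparsity pattern is preserved exactly, and the
#' transform is monotone within each cell.
#'
#' @param counts nonnegative count matrix, cells x genes (dense or
#'   sparse).
#' @param scale.factor positive scale factor applied to every cell;
#'   10,000 is the de-facto standard for this normalization family.
#' @return Matrix of the same class and dimensions with nonnegative
#'   normalized expression.
#' @examples
#' counts <- rbind(c(1, 99), c(1, 99))
#' log_normalize(counts, scale.factor = 100)[1, 1]  # log(2)
#' @export
log_normalize <- function(counts, scale.factor = 1e4) {
  validate_expression_matrix(counts, arg = "counts")
  if (!is.numeric(scale.factor) || length(scale.factor) != 1L ||
      !is.finite(scale.factor) || scale.factor <= 0) {
    stop("'scale.factor' must be a single positive number", call. = FALSE)
  }
  totals <- rowSums(counts)
  if (any(totals == 0)) {
    bad <- cell_ids(counts)[totals == 0]
    stop("cell(s) with zero total counts cannot be normalized: ",
         paste(head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) sprintf(" (and %d more)", length(bad) - 10L),
         call. = FALSE)
  }
  if (is_sparse(counts)) {
    out <- Matrix::Diagonal(x = scale.factor / totals) %*% counts
    out <- log1p(out)
    dimnames(out) <- dimnames(counts)
    as(out, "CsparseMatrix")
  } else {
    log1p(counts * (scale.factor / totals))
  }
}

#' Simple quality-control filtering of cells and genes
#'
#' Drops cells expressing fewer than `min.genes.per.cell` genes, then
#' genes detected in fewer than `min.cells.per.gene` of the remaining
#' cells. Thresholds of 0 keep everything.
#'
#' @param counts count or expression matrix, cells x genes.
#' @param min.genes.per.cell minimum number of genes with nonzero counts
#'   a cell must have to be kept.
#' @param min.cells.per.gene minimum number of cells with nonzero counts
#'   a gene must have to be kept.
#' @return The filtered matrix.
#' @export
qc_filter <- function(counts, min.genes.per.cell = 0L,
                      min.cells.per.gene = 0L) {
  validate_expression_matrix(counts, arg = "counts")
  keep_cells <- rowSums(counts > 0) >= min.genes.per.cell
  out <- counts[keep_cells, , drop = FALSE]
  keep_genes <- colSums(out > 0) >= min.cells.per.gene
  out[, keep_genes, drop = FALSE]
}
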