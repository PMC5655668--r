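#' Assemble an expression dataset
#'
#' Bundles the isoform- and gene-level expression matrices (both on the
#' log2(FPKM+1) scale), the isoform-to-gene map, and the tissue of origin of
#' each cell line into a single validated container.  All matrices share the
#' same cell-line columns; the gene matrix, if omitted, is recomputed from
#' the isoform matrix by summing isoform FPKM within each gene (see
#' [aggregate_isoforms()]).
#'
#' @param isoform_matrix numeric matrix, isoforms x cell lines, log2(FPKM+1).
#' @param isoform_map data.frame with columns `isoform_id`, `gene_id`; every
#'   isoform maps to exactly one gene.
#' @param tissues named character vector, tissue label per cell line.
#' @param gene_matrix optional numeric matrix, genes x cell lines; recomputed
#'   from `isoform_matrix` when `NULL`.
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `isoform_matrix`, `gene_matrix`, `isoform_map`, `tissues`.
#' @export
expression_dataset <- function(isoform_matrix, isoform_map, tissues,
                               gene_matrix = NULL) {
  stopifnot(is.matrix(isoform_matrix), is.data.frame(isoform_map))
  if (!all(c("isoform_id", "gene_id") %in% names(isoform_map))) {
    stop("isoform_map needs columns 'isoform_id' and 'gene_id'")
  }
  if (anyDuplicated(isoform_map$isoform_id)) {
    stop("every isoform must map to exactly one gene")
  }
  if (!all(rownames(isoform_matrix) %in% isoform_map$isoform_id)) {
    stop("unmapped isoforms in isoform_matrix")
  }
  cells <- colnames(isoform_matrix)
  if (is.null(cells)) stop("isoform_matrix needs cell-line column names")
  if (is.null(names(tissues))) {
    if (length(tissues) != length(cells)) stop("tissues misaligned")
    names(tissues) <- cells
  }
  if (!all(cells %in% names(tissues))) stop("missing tissue labels")
  tissues <- tissues[cells]
  if (anyNA(tissues)) stop("missing tissue labels")
  if (is.null(gene_matrix)) {
    gene_matrix <- aggregate_isoforms(isoform_matrix, isoform_map)
  }
  if (!identical(colnames(gene_matrix), cells)) {
    stop("gene and isoform matrices must share identical cell-line columns")
  }
  structure(
    list(isoform_matrix = isoform_matrix, gene_matrix = gene_matrix,
         isoform_map = isoform_map[match(rownames(isoform_matrix),
                                         isoform_map$isoform_id), ,
                                   drop = FALSE],
         tissues = tissues),
    class = "ExpressionDataset")
}

#' Aggregate isoform expression to gene level
#'
#' Gene expression is defined on the FPKM scale as the sum of the FPKM of the
#' gene's isoforms, reported back on the log2(FPKM+1) scale:
#' `gene = log2(1 + sum(2^isoform - 1))`.  A single-isoform gene therefore
#' has gene expression identical to its isoform.
#'
#' @param isoform_matrix numeric matrix, isoforms x cell lines, log2(FPKM+1).
#' @param isoform_map data.frame with `isoform_id`, `gene_id`.
#' @return Numeric matrix, genes x cell lines, log2(FPKM+1).
#' @export
aggregate_isoforms <- function(isoform_matrix, isoform_map) {
  gene <- isoform_map$gene_id[match(rownames(isoform_matrix),
                                    isoform_map$isoform_id)]
  if (anyNA(gene)) stop("unmapped isoforms in isoform_matrix")
  fpkm <- 2^isoform_matrix - 1
  gsum <- rowsum(fpkm, group = gene, reorder = TRUE)
  log2(1 + gsum)
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf(
    "ExpressionDataset: %d isoforms / %d genes x %d cell lines (%d tissues)\n",
    nrow(x$isoform_matrix), nrow(x$gene_matrix), ncol(x$isoform_matrix),
    length(unique(x$tissues))))
  invisible(x)
}

# subset an ExpressionDataset to a set of cell lines (internal)
.subset_cells <- function(expr, cells) {
  expression_dataset(expr$isoform_matrix[, cells, drop = FALSE],
                     expr$isoform_map, expr$tissues[cells],
                     gene_matrix = expr$gene_matrix[, cells, drop = FALSE])
}

# fetch one feature row by level (internal)
.feature_values <- function(expr, feature, level = c("gene", "isoform")) {
  level <- match.arg(level)
  m <- if (level == "gene") expr$gene_matrix else expr$isoform_matrix
  if (!feature %in% rownames(m)) {
    stop(sprintf("feature '%s' not found at %s level", feature, level))
  }
  m[feature, ]
}

#' Assemble a drug-sensitivity table
#'
#' One row per (cell line, drug, study): the area above the dose-response
#' curve (AAC) in `[0,1]`, where higher values mean higher sensitivity.
#'
#' @param cell_line,drug,aac,study_id vectors of equal length.
#' @return A data.frame of class `SensitivityTable` with those four columns.
#' @export
sensitivity_table <- function(cell_line, drug, aac, study_id) {
  df <- data.frame(cell_line = as.character(cell_line),
                   drug = as.character(drug),
                   aac = as.numeric(aac),
                   study_id = as.character(study_id),
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$aac)) || any(df$aac < 0 | df$aac > 1)) {
    stop("aac values must lie in [0, 1]")
  }
  key <- paste(df$cell_line, df$drug, df$study_id, sep = "\r")
  if (anyDuplicated(key)) stop("(cell_line, drug, study_id) must be unique")
  class(df) <- c("SensitivityTable", "data.frame")
  df
}
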