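#' Single-cell count matrix
#'
#' Container for raw droplet scRNA-seq counts: a sparse cells x genes
#' matrix of non-negative integers together with cell barcodes, gene
#' names and a per-gene mitochondrial flag. Mitochondrial genes are
#' detected from an `mt-`/`MT-` gene-name prefix unless an explicit
#' flag vector is supplied.
#'
#' @param counts cells x genes matrix (dense or sparse) of non-negative
#'   integer counts.
#' @param barcodes character vector of unique cell barcodes (rows).
#' @param gene_names character vector of unique gene names (columns).
#' @param is_mito optional logical vector flagging mitochondrial genes;
#'   defaults to the `mt-`/`MT-` prefix convention.
#' @return An object of class `sc_counts`.
#' @export
sc_counts <- function(counts, barcodes = rownames(counts),
                      gene_names = colnames(counts), is_mito = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(barcodes) || is.null(gene_names))
    stopf("barcodes and gene_names are required (or set as dimnames)")
  barcodes <- as.character(barcodes)
  gene_names <- as.character(gene_names)
  if (length(barcodes) != nrow(counts))
    stopf("length(barcodes) != number of cells (rows)")
  if (length(gene_names) != ncol(counts))
    stopf("length(gene_names) != number of genes (columns)")
  if (anyDuplicated(barcodes)) stopf("barcodes must be unique")
  if (anyDuplicated(gene_names)) stopf("gene names must be unique")
  if (any(counts@x < 0)) stopf("counts must be non-negative")
  if (is.null(is_mito)) is_mito <- detect_mito(gene_names)
  if (length(is_mito) != length(gene_names))
    stopf("is_mito length must equal the number of genes")
  dimnames(counts) <- list(barcodes, gene_names)
  structure(list(counts = counts, barcodes = barcodes,
                 gene_names = gene_names, is_mito = as.logical(is_mito)),
            class = "sc_counts")
}

#' Flag mitochondrial genes by name prefix
#'
#' @param gene_names character vector of gene names.
#' @return Logical vector, `TRUE` for names starting with `mt-` or `MT-`.
#' @export
detect_mito <- function(gene_names) {
  startsWith(gene_names, "mt-") | startsWith(gene_names, "MT-")
}

#' @export
print.sc_counts <- function(x, ...) {
  cat(sprintf("sc_counts: %d cells x %d genes (%d mitochondrial)\n",
              nrow(x$counts), ncol(x$counts), sum(x$is_mito)))
  invisible(x)
}

#' @export
dim.sc_counts <- function(x) dim(x$counts)

#' Per-cell QC metrics
#'
#' @param m an [sc_counts] object.
#' @return data.frame with `barcode`, `n_detected` (genes with count > 0),
#'   `total_counts` and `mito_frac` (0 for empty cells).
#' @export
qc_metrics <- function(m) {
  stopifnot(inherits(m, "sc_counts"))
  total <- Matrix::rowSums(m$counts)
  detected <- Matrix::rowSums(m$counts > 0)
  mito <- if (any(m$is_mito))
    Matrix::rowSums(m$counts[, m$is_mito, drop = FALSE]) else 0
  mito_frac <- ifelse(total > 0, mito / total, 0)
  data.frame(barcode = m$barcodes, n_detected = as.integer(detected),
             total_counts = total, mito_frac = mito_frac,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cell QC thresholds
#'
#' Thresholds for droplet cell filtering. All three comparisons are
#' strict, matching the usual wording: a retained cell has *more than*
#' `min_genes` detected genes, *fewer than* `max_genes` detected genes
#' and a mitochondrial fraction *below* `max_mito_frac`.
#'
#' @param min_genes exclusive lower bound on detected genes (default 200).
#' @param max_genes exclusive upper bound on detected genes (default 6500).
#' @param max_mito_frac exclusive upper bound on the mitochondrial
#'   count fraction (default 0.40).
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes = 200, max_genes = 6500,
                          max_mito_frac = 0.40) {
  assert_scalar_num(min_genes, "min_genes", min = 0, integer = TRUE)
  assert_scalar_num(max_genes, "max_genes", min = min_genes,
                    strict_min = TRUE, integer = TRUE)
  assert_scalar_num(max_mito_frac, "max_mito_frac", min = 0, max = 1,
                    strict_min = TRUE)
  structure(list(min_genes = as.integer(min_genes),
                 max_genes = as.integer(max_genes),
                 max_mito_frac = max_mito_frac),
            class = "qc_thresholds")
}

#' Filter cells on QC thresholds
#'
#' Retains exactly the cells with detected-gene count strictly above
#' `min_genes`, strictly below `max_genes`, and mitochondrial count
#' fraction strictly below `max_mito_frac`. The gene set and the order
#' of surviving cells are unchanged, so the filter is idempotent.
#'
#' @param m an [sc_counts] object.
#' @param thresholds a [qc_thresholds] object.
#' @return Filtered [sc_counts]; a warning (not an error) if no cell
#'   survives.
#' @export
qc_filter <- function(m, thresholds = qc_thresholds()) {
  stopifnot(inherits(m, "sc_counts"), inherits(thresholds, "qc_thresholds"))
  qm <- qc_metrics(m)
  keep <- qm$n_detected > thresholds$min_genes &
    qm$n_detected < thresholds$max_genes &
    qm$mito_frac < thresholds$max_mito_frac
  if (nrow(qm) > 0 && !any(keep))
    warnf("qc_filter removed all %d cells", nrow(qm))
  sc_counts(m$counts[keep, , drop = FALSE],
            barcodes = m$barcodes[keep],
            gene_names = m$gene_names,
            is_mito = m$is_mito)
}
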