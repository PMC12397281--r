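#' Per-type expression fold changes
#'
#' For each gene and cell type, computes the mean expression inside the
#' type versus all other labeled cells, on the linear scale (`expm1` of
#' the log-normalized values, i.e. CPM when the scale factor is 1e6),
#' plus the fraction of the type's cells expressing the gene (nonzero
#' raw count). The fold change uses a pseudocount:
#' `fc = (mean_in + eps) / (mean_out + eps)` with `eps = 1` CPM by
#' default, which avoids division by zero and caps the fold change when
#' the baseline is pure drop-out.
#'
#' @param nm an [sc_norm] object.
#' @param ca a [cluster_assignment] labeling every cell of `nm`.
#' @param genes optional gene subset (e.g. ligand/receptor genes only).
#' @param eps pseudocount on the linear (CPM) scale, default 1.
#' @param min_cells types with fewer cells are excluded with a warning
#'   (default 3).
#' @return data.frame of class `fold_change_table` with columns `gene`,
#'   `cell_type`, `mean_in`, `mean_out`, `fc`, `log2fc`,
#'   `frac_expressing`.
#' @export
compute_fold_changes <- function(nm, ca, genes = NULL, eps = 1,
                                 min_cells = 3) {
  stopifnot(inherits(nm, "sc_norm"), inherits(ca, "cluster_assignment"))
  bc <- rownames(nm$values)
  labels <- ca$labels[bc]
  if (anyNA(labels))
    stopf("%d cell(s) of the matrix have no label", sum(is.na(labels)))
  if (is.null(genes)) genes <- colnames(nm$values)
  missing <- setdiff(genes, colnames(nm$values))
  if (length(missing) > 0)
    stopf("unknown gene(s): %s", paste(utils::head(missing, 3),
                                       collapse = ", "))
  keep_types <- names(which(table(labels) >= min_cells))
  dropped <- setdiff(unique(labels), keep_types)
  if (length(dropped) > 0)
    warnf("excluding %d cell type(s) with < %d cells: %s",
          length(dropped), min_cells, paste(dropped, collapse = ", "))
  keep <- labels %in% keep_types
  e <- expm1(nm$values[keep, genes, drop = FALSE])
  x <- nm$counts$counts[bc[keep], genes, drop = FALSE] > 0
  f <- factor(labels[keep], levels = sort(keep_types))
  st <- fc_stats(as.matrix(e), as.matrix(x) * 1, f, eps = eps)
  types <- levels(f)
  data.frame(gene = rep(genes, each = length(types)),
             cell_type = rep(types, length(genes)),
             mean_in = as.vector(st$mean_in),
             mean_out = as.vector(st$mean_out),
             fc = as.vector(st$fc), log2fc = as.vector(st$log2fc),
             frac_expressing = as.vector(st$frac),
             row.names = NULL, stringsAsFactors = FALSE) |>
    structure(class = c("fold_change_table", "data.frame"), eps = eps)
}

# Core fold-change moments for a dense linear-scale matrix `e` and
# expression indicator `x` (cells x genes), given a type factor.
# Shared by compute_fold_changes and the permutation fast path.
fc_stats <- function(e, x, f, eps = 1) {
  ns <- tabulate(f, nbins = nlevels(f))
  n <- length(f)
  sums <- rowsum(e, f)                      # types x genes
  tot <- colSums(e)
  mean_in <- sums / ns
  denom_out <- n - ns
  mean_out <- sweep(-sums, 2, tot, "+") / ifelse(denom_out > 0, denom_out, 1)
  mean_out[denom_out == 0, ] <- 0
  fc <- (mean_in + eps) / (mean_out + eps)
  frac <- rowsum(x, f) / ns
  list(mean_in = mean_in, mean_out = mean_out, fc = fc,
       log2fc = log2(fc), frac = frac, ns = ns)
}

#' Expression call for a gene in a cell type
#'
#' A gene counts as expressed by a cell type when at least `min_frac` of
#' the type's cells have a nonzero count **and** its log2 fold change
#' against all other cells exceeds `min_log2fc`. The fraction bound is
#' inclusive (`>=`), the fold-change bound strict (`>`).
#'
#' @param fct a [compute_fold_changes] table.
#' @param gene,cell_type the row to query.
#' @param min_frac minimum expressing fraction (default 0.10, inclusive).
#' @param min_log2fc log2 fold-change bound (default 0, exclusive).
#' @return `TRUE`/`FALSE`; a missing (gene, cell_type) row yields `FALSE`
#'   with a warning.
#' @export
is_expressed <- function(fct, gene, cell_type, min_frac = 0.10,
                         min_log2fc = 0) {
  row <- fct[fct$gene == gene & fct$cell_type == cell_type, ]
  if (nrow(row) == 0) {
    warnf("no fold-change row for gene '%s' in type '%s'", gene, cell_type)
    return(FALSE)
  }
  row$frac_expressing[1] >= min_frac & row$log2fc[1] > min_log2fc
}
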