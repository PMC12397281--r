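# Shared fixtures, built in code at test time.

# sc_counts from a plain matrix with auto names.
toy_counts <- function(mat, barcodes = NULL, genes = NULL, is_mito = NULL) {
  if (is.null(barcodes)) barcodes <- sprintf("c%02d", seq_len(nrow(mat)))
  if (is.null(genes)) genes <- sprintf("G%02d", seq_len(ncol(mat)))
  sc_counts(mat, barcodes = barcodes, gene_names = genes, is_mito = is_mito)
}

# sc_norm with prescribed linear-scale (CPM) values per cell x gene.
# Counts are set to the ceiling of the linear values so that
# frac_expressing reflects linear > 0 exactly.
toy_norm <- function(linear, barcodes = NULL, genes = NULL) {
  if (is.null(barcodes)) barcodes <- sprintf("c%02d", seq_len(nrow(linear)))
  if (is.null(genes)) genes <- sprintf("G%02d", seq_len(ncol(linear)))
  counts <- toy_counts(ceiling(linear), barcodes, genes)
  values <- Matrix::Matrix(log1p(linear), sparse = TRUE)
  dimnames(values) <- list(barcodes, genes)
  structure(list(values = methods::as(values, "CsparseMatrix"),
                 scale_factor = 1e6, counts = counts),
            class = "sc_norm")
}

labels_for <- function(nm_or_counts, labels) {
  bc <- if (inherits(nm_or_counts, "sc_norm"))
    rownames(nm_or_counts$values) else nm_or_counts$barcodes
  cluster_assignment(stats::setNames(labels, bc))
}

# Small default simulation used across tests.
small_sim_spec <- function(seed = 1, ...) {
  simulation_spec(n_cell_types = 3, cells_per_type = 80, n_genes = 150,
                  n_mito_genes = 10, markers_per_type = 10, seed = seed, ...)
}

# Independent oracle: brute-force triple loop over (pair, source, target)
# re-deriving expression calls and edge weights from the fold-change
# table alone.
brute_force_weights <- function(fct, lr, assoc, min_frac = 0.10,
                                min_log2fc = 0) {
  lr <- unique(lr[, c("ligand_gene", "receptor_gene")])
  types <- sort(unique(fct$cell_type))
  row_of <- function(gene, type)
    fct[fct$gene == gene & fct$cell_type == type, ]
  w <- matrix(0, length(types), length(types),
              dimnames = list(types, types))
  np <- matrix(0L, length(types), length(types),
               dimnames = list(types, types))
  for (k in seq_len(nrow(lr))) {
    s <- assoc_lookup(assoc, lr$ligand_gene[k], lr$receptor_gene[k])
    w_lr <- if (is.na(s)) 0 else s / 1000
    for (src in types) for (tgt in types) {
      rl <- row_of(lr$ligand_gene[k], src)
      rr <- row_of(lr$receptor_gene[k], tgt)
      if (nrow(rl) == 0 || nrow(rr) == 0) next
      lig_ok <- rl$frac_expressing >= min_frac & rl$log2fc > min_log2fc
      rec_ok <- rr$frac_expressing >= min_frac & rr$log2fc > min_log2fc
      if (lig_ok && rec_ok) {
        np[src, tgt] <- np[src, tgt] + 1L
        w[src, tgt] <- w[src, tgt] +
          max(rl$log2fc, 0) * w_lr * max(rr$log2fc, 0)
      }
    }
  }
  list(weight = w, n_pairs = np)
}

# Random fold-change table over n_types x n_genes for oracle tests.
random_fct <- function(n_types, n_genes, seed) {
  set.seed(seed)
  types <- paste0("T", seq_len(n_types))
  genes <- paste0("g", seq_len(n_genes))
  grid <- expand.grid(cell_type = types, gene = genes,
                      stringsAsFactors = FALSE)
  mean_in <- rlnorm(nrow(grid), 2, 1)
  mean_out <- rlnorm(nrow(grid), 2, 1)
  fc <- (mean_in + 1) / (mean_out + 1)
  structure(data.frame(gene = grid$gene, cell_type = grid$cell_type,
                       mean_in = mean_in, mean_out = mean_out, fc = fc,
                       log2fc = log2(fc),
                       frac_expressing = round(runif(nrow(grid)), 2),
                       stringsAsFactors = FALSE),
            class = c("fold_change_table", "data.frame"), eps = 1)
}
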