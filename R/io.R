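#' Read a 10x-style MatrixMarket count directory
#'
#' Expects `matrix.mtx`, `barcodes.tsv` and `features.tsv` (each
#' optionally gzipped) in `dir`. The MatrixMarket file is 1-based
#' coordinate triplets with genes in rows and cells in columns (the 10x
#' convention); internally counts are held cells x genes. Gene names
#' come from the second column of `features.tsv` (first column when
#' there is only one); duplicated names are disambiguated by suffixing
#' (`Gm1`, `Gm1.1`, ...). Mitochondrial flags follow the `mt-`/`MT-`
#' prefix rule.
#'
#' @param dir directory containing the three files.
#' @return An [sc_counts] object.
#' @export
read_counts_10x <- function(dir) {
  find <- function(base) {
    for (f in file.path(dir, c(base, paste0(base, ".gz"))))
      if (file.exists(f)) return(f)
    stopf("missing %s(.gz) in %s", base, dir)
  }
  mtx <- find("matrix.mtx")
  validate_mtx(mtx)
  m <- Matrix::readMM(mtx)
  bc <- read.delim(find("barcodes.tsv"), header = FALSE,
                   stringsAsFactors = FALSE)[[1]]
  feat <- read.delim(find("features.tsv"), header = FALSE,
                     stringsAsFactors = FALSE)
  gn <- if (ncol(feat) >= 2) feat[[2]] else feat[[1]]
  if (length(gn) != nrow(m) || length(bc) != ncol(m))
    stopf("matrix is %d x %d but features/barcodes have %d/%d entries",
          nrow(m), ncol(m), length(gn), length(bc))
  gn <- make.unique(gn)
  sc_counts(Matrix::t(m), barcodes = bc, gene_names = gn)
}

# Light structural validation of a MatrixMarket coordinate file: the
# entry count promised by the size header must match the data lines.
validate_mtx <- function(path) {
  con <- if (endsWith(path, ".gz")) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  lines <- readLines(con)
  body <- which(!startsWith(lines, "%") & nzchar(trimws(lines)))
  if (length(body) == 0) stopf("%s: no size header found", path)
  hdr <- as.numeric(strsplit(trimws(lines[body[1]]), "\\s+")[[1]])
  if (length(hdr) != 3 || anyNA(hdr))
    stopf("%s: malformed size header at line %d", path, body[1])
  n_data <- length(body) - 1L
  if (n_data != hdr[3])
    stopf("%s: header (line %d) declares %d entries but %d are present",
          path, body[1], hdr[3], n_data)
  invisible(TRUE)
}

#' Write counts as a 10x-style MatrixMarket directory
#'
#' @param m an [sc_counts] object.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_counts_10x <- function(m, dir) {
  stopifnot(inherits(m, "sc_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "barcodes.tsv", "features.tsv"))
  Matrix::writeMM(Matrix::t(m$counts), paths[1])
  writeLines(m$barcodes, paths[2])
  write.table(data.frame(m$gene_names, m$gene_names, "Gene Expression"),
              paths[3], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(paths)
}

#' Read a dense TSV count matrix
#'
#' Fallback dense format: genes in rows (first column `gene`), cells in
#' columns (header = barcodes).
#'
#' @param path TSV file (optionally gzipped).
#' @return An [sc_counts] object.
#' @export
read_counts_tsv <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- make.unique(as.character(d[[1]]))
  mat <- t(as.matrix(d[, -1, drop = FALSE]))
  sc_counts(mat, barcodes = rownames(mat), gene_names = genes)
}

#' Write a dense TSV count matrix
#'
#' @param m an [sc_counts] object.
#' @param path output TSV path.
#' @export
write_counts_tsv <- function(m, path) {
  stopifnot(inherits(m, "sc_counts"))
  d <- data.frame(gene = m$gene_names,
                  as.matrix(Matrix::t(m$counts)), check.names = FALSE)
  colnames(d) <- c("gene", m$barcodes)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read / write cell labels
#'
#' Two-column TSV (`barcode`, `label`).
#'
#' @param path TSV path.
#' @return A [cluster_assignment].
#' @export
read_labels_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  for (col in c("barcode", "label"))
    if (!col %in% names(d)) stopf("labels file lacks column '%s'", col)
  cluster_assignment(stats::setNames(as.character(d$label), d$barcode),
                     params = list(source = path))
}

#' @rdname read_labels_tsv
#' @param ca a [cluster_assignment] to write.
#' @export
write_labels_tsv <- function(ca, path) {
  stopifnot(inherits(ca, "cluster_assignment"))
  write.table(data.frame(barcode = names(ca$labels), label = ca$labels),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read the ligand-receptor and association-score tables
#'
#' The ligand-receptor table needs columns `ligand_gene` and
#' `receptor_gene`; duplicate pairs are dropped with a logged count.
#' The association table needs `gene_a`, `gene_b` and `combined_score`
#' in \[0, 1000\] (the STRING protein-links dialect); when an alias
#' table (`protein_id`, `gene_symbol`) is supplied, protein ids in the
#' association table are mapped to gene symbols and unmapped rows are
#' dropped with a logged count.
#'
#' @param lr_path ligand-receptor TSV.
#' @param assoc_path association-score TSV.
#' @param alias_path optional protein-to-gene alias TSV.
#' @return list with `lr`, `assoc`, and bookkeeping counts
#'   (`n_duplicate_lr`, `n_unmapped_assoc`).
#' @export
read_knowledge_tables <- function(lr_path, assoc_path, alias_path = NULL) {
  lr <- read.delim(lr_path, stringsAsFactors = FALSE)
  for (col in c("ligand_gene", "receptor_gene"))
    if (!col %in% names(lr)) stopf("LR table lacks column '%s'", col)
  n_dup <- nrow(lr) - nrow(unique(lr[, c("ligand_gene", "receptor_gene")]))
  if (n_dup > 0) {
    message(sprintf("dropping %d duplicate ligand-receptor pair(s)", n_dup))
    lr <- lr[!duplicated(lr[, c("ligand_gene", "receptor_gene")]), ,
             drop = FALSE]
  }
  assoc <- read.delim(assoc_path, stringsAsFactors = FALSE)
  for (col in c("gene_a", "gene_b", "combined_score"))
    if (!col %in% names(assoc)) stopf("association table lacks column '%s'",
                                      col)
  if (any(assoc$combined_score < 0 | assoc$combined_score > 1000))
    stopf("association scores must lie in [0, 1000]")
  n_unmapped <- 0L
  if (!is.null(alias_path)) {
    alias <- read.delim(alias_path, stringsAsFactors = FALSE)
    for (col in c("protein_id", "gene_symbol"))
      if (!col %in% names(alias)) stopf("alias table lacks column '%s'", col)
    map <- stats::setNames(alias$gene_symbol, alias$protein_id)
    a <- map[assoc$gene_a]
    b <- map[assoc$gene_b]
    ok <- !is.na(a) & !is.na(b)
    n_unmapped <- sum(!ok)
    if (n_unmapped > 0)
      message(sprintf("dropping %d association row(s) with unmapped ids",
                      n_unmapped))
    assoc <- data.frame(gene_a = unname(a[ok]), gene_b = unname(b[ok]),
                        combined_score = assoc$combined_score[ok],
                        stringsAsFactors = FALSE)
  }
  list(lr = lr[, c("ligand_gene", "receptor_gene"), drop = FALSE],
       assoc = assoc[, c("gene_a", "gene_b", "combined_score")],
       n_duplicate_lr = n_dup, n_unmapped_assoc = n_unmapped)
}

#' Read / write a flat key = value configuration file
#'
#' @param path config file; one `key = value` pair per line, `#`
#'   comments allowed.
#' @return Named list of character values.
#' @export
read_config_file <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- vapply(kv, length, 0L) != 3L
  if (any(bad)) stopf("malformed config line: '%s'", lines[bad][1])
  stats::setNames(lapply(kv, function(x) trimws(x[3])),
                  vapply(kv, function(x) trimws(x[2]), ""))
}

#' @rdname read_config_file
#' @param config named list of scalar values to write.
#' @export
write_config_file <- function(config, path) {
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, function(v) paste(format(v),
                                                      collapse = ","), "")),
             path)
}
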