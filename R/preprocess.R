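#' Cell-type / cluster assignment
#'
#' Maps every (post-QC) barcode to exactly one non-empty label, together
#' with the parameters that produced the assignment.
#'
#' @param labels named character vector: `names()` are barcodes, values
#'   are cluster or cell-type labels.
#' @param params list of parameters used to derive the assignment.
#' @return An object of class `cluster_assignment`.
#' @export
cluster_assignment <- function(labels, params = list()) {
  labels <- vapply(labels, as.character, "", USE.NAMES = TRUE)
  if (is.null(names(labels)) || anyDuplicated(names(labels)))
    stopf("labels must be named by unique barcodes")
  if (any(!nzchar(labels)) || anyNA(labels))
    stopf("labels must be non-empty strings")
  structure(list(labels = labels, params = params),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  tab <- sort(table(x$labels), decreasing = TRUE)
  cat(sprintf("cluster_assignment: %d cells, %d labels\n",
              length(x$labels), length(tab)))
  print(utils::head(tab, 10))
  invisible(x)
}

#' Log-CPM normalization
#'
#' Per-cell library-size normalization followed by a log transform, the
#' standard droplet normalization: `value(i, g) = ln(count(i, g) /
#' total(i) * scale_factor + 1)` with `scale_factor` defaulting to one
#' million (log-CPM). Rows of all-zero cells stay all-zero. For every
#' cell with positive total, `sum(expm1(row)) == scale_factor` exactly
#' (up to floating point), which downstream code relies on to move
#' between log and linear scale.
#'
#' @param m an [sc_counts] object.
#' @param scale_factor positive scale factor, default `1e6`.
#' @return An object of class `sc_norm`: `values` (sparse cells x genes),
#'   `scale_factor`, and `counts` (the source [sc_counts], kept for
#'   expressing-fraction computations).
#' @export
normalize_counts <- function(m, scale_factor = 1e6) {
  stopifnot(inherits(m, "sc_counts"))
  assert_scalar_num(scale_factor, "scale_factor", min = 0, strict_min = TRUE)
  total <- Matrix::rowSums(m$counts)
  scl <- ifelse(total > 0, scale_factor / total, 0)
  values <- log1p(Matrix::Diagonal(x = scl) %*% m$counts)
  values <- methods::as(values, "CsparseMatrix")
  dimnames(values) <- dimnames(m$counts)
  structure(list(values = values, scale_factor = scale_factor, counts = m),
            class = "sc_norm")
}

#' @export
print.sc_norm <- function(x, ...) {
  cat(sprintf("sc_norm: %d cells x %d genes, log scale (scale factor %g)\n",
              nrow(x$values), ncol(x$values), x$scale_factor))
  invisible(x)
}

#' Covariate regression and per-gene scaling
#'
#' For each gene, takes ordinary-least-squares residuals of the
#' normalized expression on a per-cell covariate (with intercept) —
#' regressing out per-cell read depth as a confounder — then z-scores
#' the residuals per gene. Zero-variance genes map to all-zero columns.
#' A constant covariate degenerates to plain per-gene z-scoring.
#'
#' @param nm an [sc_norm] object.
#' @param genes optional character vector restricting to a gene subset
#'   (typically the highly variable genes).
#' @param covariate numeric per-cell confounder; defaults to the
#'   per-cell total raw counts of the source matrix.
#' @return Dense cells x genes matrix of scaled residuals.
#' @export
scale_and_regress <- function(nm, genes = NULL, covariate = NULL) {
  stopifnot(inherits(nm, "sc_norm"))
  if (is.null(covariate))
    covariate <- Matrix::rowSums(nm$counts$counts)
  if (length(covariate) != nrow(nm$values))
    stopf("covariate length (%d) must equal the number of cells (%d)",
          length(covariate), nrow(nm$values))
  y <- nm$values
  if (!is.null(genes)) {
    missing <- setdiff(genes, colnames(y))
    if (length(missing) > 0)
      stopf("unknown gene(s): %s", paste(utils::head(missing, 3),
                                         collapse = ", "))
    y <- y[, genes, drop = FALSE]
  }
  y <- as.matrix(y)
  qr_x <- qr(cbind(1, covariate))
  res <- qr.resid(qr_x, y)
  sds <- apply(res, 2, sd)
  # genes (numerically) fully explained by the covariate map to zeros
  zero <- sds <= 1e-8 * pmax(apply(y, 2, sd), .Machine$double.xmin)
  scaled <- sweep(res, 2, ifelse(zero, 1, sds), "/")
  scaled[, zero] <- 0
  dimnames(scaled) <- dimnames(y)
  scaled
}

#' Select highly variable genes
#'
#' Ranks genes by standardized variance: the per-gene variance of
#' normalized values divided by a mean-variance trend fitted as the mean
#' variance within 20 equal-frequency bins of gene mean. Ties are broken
#' by gene name (lexicographic), making the selection deterministic.
#'
#' @param nm an [sc_norm] object.
#' @param n_top number of genes to keep (default 2000).
#' @param n_bins number of mean bins for the trend (default 20).
#' @return Character vector of selected gene names (length
#'   `min(n_top, n_genes)`, with a warning when `n_top > n_genes`).
#' @export
select_hvg <- function(nm, n_top = 2000, n_bins = 20) {
  stopifnot(inherits(nm, "sc_norm"))
  assert_scalar_num(n_top, "n_top", min = 1, integer = TRUE)
  v <- nm$values
  n <- nrow(v)
  if (n == 0) stopf("no cells available for HVG selection")
  genes <- colnames(v)
  if (n_top > length(genes)) {
    warnf("n_top = %d exceeds the %d available genes; returning all",
          n_top, length(genes))
    n_top <- length(genes)
  }
  mu <- Matrix::colMeans(v)
  ex2 <- Matrix::colMeans(v^2)
  vars <- (ex2 - mu^2) * n / max(n - 1, 1)
  # equal-frequency bins on the mean; degenerate bins collapse safely
  n_bins <- max(1L, min(n_bins, length(unique(mu))))
  brk <- unique(quantile(mu, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- if (length(brk) > 2) cut(mu, brk, include.lowest = TRUE)
  else factor(rep(1, length(mu)))
  trend <- tapply(vars, bin, mean)
  expected <- trend[as.integer(bin)]
  std_var <- ifelse(expected > 0, vars / expected, 0)
  genes[order(-std_var, genes)][seq_len(n_top)]
}

#' Principal component analysis of the scaled matrix
#'
#' Standard PCA scores on the (HVG-restricted) scaled matrix, with a
#' fixed sign convention: each component is flipped so its largest-
#' magnitude gene loading is positive. Explained-variance shares are
#' monotone non-increasing. If the matrix rank is below `n_components`
#' the trailing components are numerically zero and a warning is
#' emitted.
#'
#' @param x dense cells x genes scaled matrix (rownames = barcodes).
#' @param n_components number of components (default 30).
#' @return An object of class `sc_embedding` with `scores` (cells x
#'   components), `var_share` (per returned component) and `sdev`.
#' @export
run_pca <- function(x, n_components = 30) {
  x <- as.matrix(x)
  assert_scalar_num(n_components, "n_components", min = 1, integer = TRUE)
  if (n_components > min(dim(x)))
    stopf("n_components = %d exceeds min(cells, genes) = %d",
          n_components, min(dim(x)))
  pc <- prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
  k <- ncol(pc$x)
  tot <- sum(pc$sdev^2)
  eff_rank <- sum(pc$sdev > max(pc$sdev[1] * 1e-10, 1e-300))
  if (eff_rank < n_components)
    warnf("input rank %d < %d requested components; trailing components are zero",
          eff_rank, n_components)
  for (j in seq_len(k)) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  rownames(pc$x) <- rownames(x)
  structure(list(scores = pc$x,
                 var_share = if (tot > 0) pc$sdev[seq_len(k)]^2 / tot
                 else rep(0, k),
                 sdev = pc$sdev[seq_len(k)],
                 rotation = pc$rotation),
            class = "sc_embedding")
}

#' @export
print.sc_embedding <- function(x, ...) {
  cat(sprintf("sc_embedding: %d cells x %d components (%.1f%% variance)\n",
              nrow(x$scores), ncol(x$scores), 100 * sum(x$var_share)))
  invisible(x)
}

#' Shared nearest-neighbor graph
#'
#' Builds the undirected weighted SNN graph used for clustering: each
#' cell's k-nearest-neighbor set (Euclidean metric in the embedding,
#' the cell itself included, distance ties broken by ascending index)
#' is compared with every other cell's set by Jaccard overlap, and
#' edges below the pruning threshold are dropped.
#'
#' @param emb an [sc_embedding] (or a numeric matrix of coordinates).
#' @param k number of neighbors (default 20); must satisfy `0 < k < n`.
#' @param prune Jaccard pruning threshold (default 1/15).
#' @return An undirected weighted [igraph::graph] whose vertex names are
#'   the barcodes.
#' @export
build_neighbors <- function(emb, k = 20, prune = 1 / 15) {
  scores <- if (inherits(emb, "sc_embedding")) emb$scores else as.matrix(emb)
  n <- nrow(scores)
  if (!is.numeric(k) || length(k) != 1 || k <= 0)
    stopf("'k' must be a positive integer")
  if (k >= n) stopf("'k' = %d must be smaller than the number of cells (%d)",
                    k, n)
  d <- as.matrix(dist(scores))
  # neighbor sets include the cell itself: n x (k+1) membership matrix
  sets <- t(vapply(seq_len(n), function(i) {
    ord <- order(d[i, ], seq_len(n))      # ties broken by index
    ord <- c(i, setdiff(ord, i))[seq_len(k + 1)]
    sort(ord)
  }, integer(k + 1)))
  a <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k + 1),
                            j = as.vector(t(sets)), x = 1,
                            dims = c(n, n))
  shared <- Matrix::tcrossprod(a)
  jac <- shared
  jac@x <- jac@x / (2 * (k + 1) - jac@x)
  jac@x[jac@x < prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  jac <- Matrix::drop0(jac)
  rownames(jac) <- colnames(jac) <- rownames(scores)
  igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                      weighted = TRUE)
}

#' Cluster the SNN graph by modularity optimization
#'
#' Louvain community detection at the given resolution (multi-level
#' modularity optimization, the FindClusters-style default). Clusters
#' are labelled `"0", "1", ...` in order of decreasing size, and the
#' result is deterministic given the seed.
#'
#' @param g weighted undirected [igraph::graph] from [build_neighbors].
#' @param resolution modularity resolution parameter (default 1.5).
#' @param seed integer RNG seed (default 0).
#' @return A [cluster_assignment] for the graph's vertices.
#' @export
cluster_graph <- function(g, resolution = 1.5, seed = 0) {
  stopifnot(inherits(g, "igraph"))
  if (igraph::vcount(g) == 0) stopf("cannot cluster an empty graph")
  assert_scalar_num(resolution, "resolution", min = 0, strict_min = TRUE)
  memb <- with_seed(seed, {
    igraph::membership(igraph::cluster_louvain(g, resolution = resolution))
  })
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(as.character(seq_along(sizes) - 1L),
                             names(sizes))
  labels <- relabel[as.character(memb)]
  names(labels) <- igraph::V(g)$name
  cluster_assignment(labels,
                     params = list(method = "louvain",
                                   resolution = resolution, seed = seed))
}

#' Run the full preprocessing chain
#'
#' QC filter, log-CPM normalization, covariate-regressed scaling on
#' highly variable genes, PCA, SNN graph and Louvain clustering, with
#' the standard droplet defaults (filters 200 / 6,500 / 40%, scale
#' factor 1e6, 2,000 HVGs, 30 PCs, k = 20, resolution 1.5).
#'
#' @param m an [sc_counts] object.
#' @param thresholds [qc_thresholds].
#' @param scale_factor normalization scale factor.
#' @param n_hvg number of highly variable genes.
#' @param n_pcs number of principal components.
#' @param k_neighbors SNN k.
#' @param snn_prune SNN Jaccard pruning threshold.
#' @param resolution clustering resolution.
#' @param seed RNG seed.
#' @return list with `counts` (filtered), `norm`, `hvg`, `embedding`,
#'   `graph` and `clusters`.
#' @export
preprocess <- function(m, thresholds = qc_thresholds(), scale_factor = 1e6,
                       n_hvg = 2000, n_pcs = 30, k_neighbors = 20,
                       snn_prune = 1 / 15, resolution = 1.5, seed = 0) {
  filtered <- qc_filter(m, thresholds)
  nm <- normalize_counts(filtered, scale_factor)
  hvg <- select_hvg(nm, n_top = n_hvg)
  scaled <- scale_and_regress(nm, genes = hvg)
  n_pcs <- min(n_pcs, dim(scaled) - 1L)
  emb <- run_pca(scaled, n_components = max(n_pcs, 1L))
  g <- build_neighbors(emb, k = min(k_neighbors, nrow(scaled) - 1L),
                       prune = snn_prune)
  cl <- cluster_graph(g, resolution = resolution, seed = seed)
  list(counts = filtered, norm = nm, hvg = hvg, embedding = emb,
       graph = g, clusters = cl)
}
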