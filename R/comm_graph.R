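#' Symmetric association-score lookup
#'
#' @param assoc data.frame with `gene_a`, `gene_b`, `combined_score`.
#' @param a,b gene names (order-free).
#' @return The combined score, or `NA` when the pair is absent.
#' @export
assoc_lookup <- function(assoc, a, b) {
  hit <- (assoc$gene_a == a & assoc$gene_b == b) |
    (assoc$gene_a == b & assoc$gene_b == a)
  if (!any(hit)) return(NA_integer_)
  assoc$combined_score[which(hit)[1]]
}

#' Build the weighted directed communication graph
#'
#' Links source cell types (expressing a ligand) to target cell types
#' (expressing the corresponding receptor) through ligand and receptor
#' nodes. A source-type -> ligand edge exists iff the ligand passes the
#' expression rule in that type, with weight `max(log2fc, 0)`;
#' receptor -> target-type edges are built analogously. The
#' ligand -> receptor edge carries the association score scaled to
#' `[0, 1]` (`combined_score / 1000`); pairs absent from the association
#' table get weight 0 (their paths contribute nothing) with a logged
#' notice. Duplicate ligand-receptor rows are collapsed.
#'
#' @param fct a [compute_fold_changes] table covering the LR genes.
#' @param lr data.frame with `ligand_gene`, `receptor_gene`.
#' @param assoc data.frame with `gene_a`, `gene_b`, `combined_score`.
#' @param min_frac,min_log2fc expression rule, see [is_expressed].
#' @param weight_type `"log2fc"` (default; clamped at 0) or `"fc"` (raw
#'   fold change) for the source/target edge weights.
#' @return An object of class `comm_graph` holding the cell-type nodes,
#'   the deduplicated pair table with `w_lr`, and the per-(pair, type)
#'   source and target edge weights.
#' @export
build_communication_graph <- function(fct, lr, assoc, min_frac = 0.10,
                                      min_log2fc = 0,
                                      weight_type = c("log2fc", "fc")) {
  stopifnot(is.data.frame(lr), is.data.frame(assoc))
  weight_type <- match.arg(weight_type)
  lr <- unique(lr[, c("ligand_gene", "receptor_gene")])
  types <- sort(unique(fct$cell_type))
  p <- nrow(lr)
  w_lr <- numeric(p)
  for (k in seq_len(p)) {
    s <- assoc_lookup(assoc, lr$ligand_gene[k], lr$receptor_gene[k])
    if (is.na(s)) {
      message(sprintf("no association score for pair %s-%s; weight set to 0",
                      lr$ligand_gene[k], lr$receptor_gene[k]))
      s <- 0
    }
    w_lr[k] <- s / 1000
  }
  # per-(type, gene) weight and expression call for the genes we need
  need <- unique(c(lr$ligand_gene, lr$receptor_gene))
  sub <- fct[fct$gene %in% need, ]
  key <- paste(sub$gene, sub$cell_type, sep = "\r")
  wval <- if (weight_type == "log2fc") pmax(sub$log2fc, 0) else sub$fc
  expr <- sub$frac_expressing >= min_frac & sub$log2fc > min_log2fc
  lookup <- function(genes, what) {
    m <- matrix(0, length(types), length(genes),
                dimnames = list(types, NULL))
    idx <- match(paste(rep(genes, each = length(types)),
                       rep(types, length(genes)), sep = "\r"), key)
    m[] <- what[idx]
    m[is.na(m)] <- 0
    m
  }
  lw <- lookup(lr$ligand_gene, wval) * lookup(lr$ligand_gene, expr)
  rw <- lookup(lr$receptor_gene, wval) * lookup(lr$receptor_gene, expr)
  lex <- lookup(lr$ligand_gene, expr) > 0
  rex <- lookup(lr$receptor_gene, expr) > 0
  lr$w_lr <- w_lr
  structure(list(types = types, pairs = lr, ligand_w = lw, receptor_w = rw,
                 ligand_expressed = lex, receptor_expressed = rex,
                 min_frac = min_frac, min_log2fc = min_log2fc,
                 weight_type = weight_type),
            class = "comm_graph")
}

#' @export
print.comm_graph <- function(x, ...) {
  cat(sprintf("comm_graph: %d cell types, %d ligand-receptor pairs\n",
              length(x$types), nrow(x$pairs)))
  invisible(x)
}

#' Connection weights between ordered cell-type pairs
#'
#' For every ordered (source, target) pair of cell types, sums the path
#' weight `w_sl * w_lr * w_rt` over all ligand-receptor pairs with a
#' complete source -> ligand -> receptor -> target path. Self
#' connections (source == target) are included and flagged.
#'
#' @param g a [build_communication_graph] object.
#' @return data.frame of class `connection_table` with columns `source`,
#'   `target`, `weight`, `n_pairs` (pairs with a complete path) and
#'   `self`; a per-pair breakdown is attached as attribute
#'   `"breakdown"`.
#' @export
connection_weights <- function(g) {
  stopifnot(inherits(g, "comm_graph"))
  types <- g$types
  t_n <- length(types)
  p <- nrow(g$pairs)
  if (p == 0) {
    w <- matrix(0, t_n, t_n)
    np <- matrix(0L, t_n, t_n)
  } else {
    w <- g$ligand_w %*% (g$pairs$w_lr * t(g$receptor_w))
    np <- (g$ligand_expressed * 1) %*% t(g$receptor_expressed * 1)
  }
  out <- data.frame(
    source = rep(types, times = t_n),
    target = rep(types, each = t_n),
    weight = as.vector(w), n_pairs = as.integer(np),
    self = rep(types, times = t_n) == rep(types, each = t_n),
    row.names = NULL, stringsAsFactors = FALSE)
  bd <- NULL
  if (p > 0) {
    pieces <- lapply(seq_len(p), function(k) {
      contrib <- outer(g$ligand_w[, k], g$receptor_w[, k]) * g$pairs$w_lr[k]
      nz <- which(contrib > 0, arr.ind = TRUE)
      if (nrow(nz) == 0) return(NULL)
      data.frame(source = types[nz[, 1]], target = types[nz[, 2]],
                 ligand = g$pairs$ligand_gene[k],
                 receptor = g$pairs$receptor_gene[k],
                 w_sl = g$ligand_w[nz[, 1], k],
                 w_lr = g$pairs$w_lr[k],
                 w_rt = g$receptor_w[nz[, 2], k],
                 path_weight = contrib[nz],
                 stringsAsFactors = FALSE)
    })
    bd <- do.call(rbind, pieces)
  }
  structure(out, class = c("connection_table", "data.frame"),
            breakdown = bd, types = types)
}

#' Incoming and outgoing communication strengths per cell type
#'
#' Sums connection weights ending at (incoming) and starting from
#' (outgoing) each cell type, over a selected connection set. By
#' default self connections are excluded from the strength summary;
#' both totals equal the summed weight of the included connections, so
#' `sum(incoming) == sum(outgoing)` always.
#'
#' @param ct a [connection_weights] table (optionally carrying
#'   `significant` calls).
#' @param only_significant restrict to connections called significant.
#' @param include_self include self connections (default `FALSE`).
#' @return data.frame with `cell_type`, `incoming`, `outgoing`.
#' @export
node_strengths <- function(ct, only_significant = FALSE,
                           include_self = FALSE) {
  stopifnot(inherits(ct, "data.frame"))
  types <- attr(ct, "types")
  if (is.null(types)) types <- sort(unique(c(ct$source, ct$target)))
  sel <- ct
  if (only_significant) {
    if (is.null(sel$significant))
      stopf("connection table carries no significance calls")
    sel <- sel[sel$significant, , drop = FALSE]
  }
  if (!include_self) sel <- sel[sel$source != sel$target, , drop = FALSE]
  incoming <- tapply(sel$weight, factor(sel$target, levels = types), sum,
                     default = 0)
  outgoing <- tapply(sel$weight, factor(sel$source, levels = types), sum,
                     default = 0)
  data.frame(cell_type = types, incoming = as.vector(incoming),
             outgoing = as.vector(outgoing),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Export the communication graph as an edge list
#'
#' @param g a [build_communication_graph] object.
#' @return data.frame with `edge_type` (`source_ligand`,
#'   `ligand_receptor`, `receptor_target`), `from`, `to`, `weight` and
#'   `provenance`.
#' @export
as_edge_list <- function(g) {
  stopifnot(inherits(g, "comm_graph"))
  rows <- list()
  for (k in seq_len(nrow(g$pairs))) {
    lig <- g$pairs$ligand_gene[k]
    rec <- g$pairs$receptor_gene[k]
    src <- which(g$ligand_expressed[, k])
    tgt <- which(g$receptor_expressed[, k])
    if (length(src) > 0)
      rows[[length(rows) + 1]] <- data.frame(
        edge_type = "source_ligand", from = g$types[src],
        to = paste0(lig, "@", g$types[src]), weight = g$ligand_w[src, k],
        provenance = sprintf("log2fc(%s,%s)", lig, g$types[src]),
        stringsAsFactors = FALSE)
    if (length(src) > 0 && length(tgt) > 0)
      rows[[length(rows) + 1]] <- data.frame(
        edge_type = "ligand_receptor", from = lig, to = rec,
        weight = g$pairs$w_lr[k],
        provenance = sprintf("combined_score(%s,%s)", lig, rec),
        stringsAsFactors = FALSE)
    if (length(tgt) > 0)
      rows[[length(rows) + 1]] <- data.frame(
        edge_type = "receptor_target", from = paste0(rec, "@", g$types[tgt]),
        to = g$types[tgt], weight = g$receptor_w[tgt, k],
        provenance = sprintf("log2fc(%s,%s)", rec, g$types[tgt]),
        stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(edge_type = character(), from = character(),
                      to = character(), weight = numeric(),
                      provenance = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
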