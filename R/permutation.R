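#' Permutation-test configuration
#'
#' @param n_permutations number of label permutations (the analysis
#'   default at full scale is 100,000; tests typically use 1,000).
#' @param alpha_adj adjusted-p significance level, default 0.01
#'   (strict: significant iff `padj < alpha_adj`).
#' @param seed integer RNG seed.
#' @param exact_enumeration enumerate all distinct label arrangements
#'   instead of Monte-Carlo sampling (feasible only for tiny label
#'   multisets).
#' @param null_scheme `"labels"` (default: shuffle cell-type labels over
#'   cells, preserving cluster sizes) or `"edge_shuffle"` (shuffle the
#'   type attachment of source and target edges; non-default
#'   alternative).
#' @param adjust_method `"BH"` (Benjamini-Hochberg, default) or
#'   `"bonferroni"`.
#' @param budget capacity guard: `n_permutations * n_types^2` above this
#'   raises an error advising a smaller `n_permutations`.
#' @return An object of class `permutation_config`.
#' @export
permutation_config <- function(n_permutations = 1000, alpha_adj = 0.01,
                               seed = 0, exact_enumeration = FALSE,
                               null_scheme = c("labels", "edge_shuffle"),
                               adjust_method = c("BH", "bonferroni"),
                               budget = 1e9) {
  assert_scalar_num(n_permutations, "n_permutations", min = 1,
                    integer = TRUE)
  assert_scalar_num(alpha_adj, "alpha_adj", min = 0, max = 1,
                    strict_min = TRUE, strict_max = TRUE)
  assert_scalar_num(seed, "seed", integer = TRUE)
  structure(list(n_permutations = as.integer(n_permutations),
                 alpha_adj = alpha_adj, seed = as.integer(seed),
                 exact_enumeration = isTRUE(exact_enumeration),
                 null_scheme = match.arg(null_scheme),
                 adjust_method = match.arg(adjust_method),
                 budget = budget),
            class = "permutation_config")
}

#' Shuffle cell-type labels across cells
#'
#' Uniform random permutation of the labels over the barcodes: the label
#' multiset (cluster sizes) is preserved exactly.
#'
#' @param ca a [cluster_assignment].
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @return A permuted [cluster_assignment].
#' @export
permute_labels <- function(ca, seed = NULL) {
  stopifnot(inherits(ca, "cluster_assignment"))
  if (length(ca$labels) == 0) stopf("empty cluster assignment")
  shuffle <- function() {
    ca$labels[] <- sample(ca$labels)
    ca
  }
  if (is.null(seed)) shuffle() else with_seed(seed, shuffle())
}

# All distinct arrangements of a label multiset, as a matrix with one
# arrangement per row. Guarded: only feasible for tiny inputs.
enumerate_label_arrangements <- function(labels, max_arrangements = 2e5) {
  tab <- table(labels)
  n_arr <- exp(lgamma(length(labels) + 1) - sum(lgamma(tab + 1)))
  if (n_arr > max_arrangements)
    stopf("%.0f distinct arrangements exceed the enumeration limit (%g)",
          n_arr, max_arrangements)
  rec <- function(counts) {
    if (sum(counts) == 0) return(list(character(0)))
    out <- list()
    for (l in names(counts)[counts > 0]) {
      counts2 <- counts
      counts2[l] <- counts2[l] - 1
      for (tail in rec(counts2)) out[[length(out) + 1]] <- c(l, tail)
    }
    out
  }
  arr <- rec(stats::setNames(as.integer(tab), names(tab)))
  do.call(rbind, arr)
}

# Deduplicated pair table with [0,1]-scaled association weights; pairs
# missing from the score table get 0 (and optionally a notice).
pair_weights <- function(lr, assoc, quiet = TRUE) {
  lr <- unique(lr[, c("ligand_gene", "receptor_gene")])
  lr$w_lr <- vapply(seq_len(nrow(lr)), function(k) {
    s <- assoc_lookup(assoc, lr$ligand_gene[k], lr$receptor_gene[k])
    if (is.na(s)) {
      if (!quiet)
        message(sprintf("no association score for pair %s-%s; weight 0",
                        lr$ligand_gene[k], lr$receptor_gene[k]))
      s <- 0
    }
    s / 1000
  }, 0)
  lr
}

# types x types connection-weight matrix from fc_stats moments.
weights_from_stats <- function(st, lig_idx, rec_idx, w_lr,
                               min_frac, min_log2fc, weight_type) {
  w <- if (weight_type == "log2fc") pmax(st$log2fc, 0) else st$fc
  m <- w * (st$frac >= min_frac & st$log2fc > min_log2fc)
  l <- m[, lig_idx, drop = FALSE]
  r <- m[, rec_idx, drop = FALSE]
  l %*% (w_lr * t(r))
}

#' Null distribution of connection weights under label permutation
#'
#' For each permutation, shuffles cell-type labels (preserving cluster
#' sizes), recomputes fold changes restricted to the ligand/receptor
#' genes only, rebuilds the graph weights and records every ordered
#' (source, target) connection weight. Streaming: full matrices are
#' never copied per permutation. Deterministic given `cfg$seed`. With
#' `cfg$exact_enumeration` the null is the complete set of distinct
#' label arrangements instead of Monte-Carlo draws.
#'
#' @param nm an [sc_norm] object.
#' @param ca a [cluster_assignment] for its cells.
#' @param lr,assoc knowledge tables (see
#'   [build_communication_graph]).
#' @param cfg a [permutation_config].
#' @param min_frac,min_log2fc expression rule, as in
#'   [build_communication_graph].
#' @param eps fold-change pseudocount.
#' @param weight_type `"log2fc"` or `"fc"`.
#' @param min_cells types with fewer cells are excluded (default 3).
#' @return An object of class `comm_null`: `null` (permutations x
#'   connections matrix), `pairs` (the (source, target) grid in matrix
#'   column order), `types`, and `exact`.
#' @export
null_distribution <- function(nm, ca, lr, assoc,
                              cfg = permutation_config(),
                              min_frac = 0.10, min_log2fc = 0, eps = 1,
                              weight_type = "log2fc", min_cells = 3) {
  stopifnot(inherits(nm, "sc_norm"), inherits(ca, "cluster_assignment"),
            inherits(cfg, "permutation_config"))
  bc <- rownames(nm$values)
  labels <- ca$labels[bc]
  if (anyNA(labels)) stopf("unlabeled cells in the matrix")
  keep_types <- names(which(table(labels) >= min_cells))
  keep <- labels %in% keep_types
  f <- factor(labels[keep], levels = sort(keep_types))
  t_n <- nlevels(f)
  if (cfg$n_permutations * t_n^2 > cfg$budget)
    stopf(paste("permutation budget exceeded (%d permutations x %d types);",
                "reduce n_permutations"), cfg$n_permutations, t_n)

  pw <- pair_weights(lr, assoc)
  genes <- unique(c(pw$ligand_gene, pw$receptor_gene))
  absent <- setdiff(genes, colnames(nm$values))
  if (length(absent) > 0) {
    message(sprintf("%d ligand/receptor gene(s) absent from the matrix; %s",
                    length(absent), "their pairs contribute nothing"))
    genes <- setdiff(genes, absent)
    pw <- pw[pw$ligand_gene %in% genes & pw$receptor_gene %in% genes, ,
             drop = FALSE]
  }
  e <- as.matrix(expm1(nm$values[keep, genes, drop = FALSE]))
  x <- (as.matrix(nm$counts$counts[bc[keep], genes, drop = FALSE]) > 0) * 1
  lig_idx <- match(pw$ligand_gene, genes)
  rec_idx <- match(pw$receptor_gene, genes)

  one <- function(fp) {
    st <- fc_stats(e, x, fp, eps = eps)
    as.vector(weights_from_stats(st, lig_idx, rec_idx, pw$w_lr,
                                 min_frac, min_log2fc, weight_type))
  }
  shuffle_edges <- function() {
    st <- fc_stats(e, x, f, eps = eps)
    w <- if (weight_type == "log2fc") pmax(st$log2fc, 0) else st$fc
    m <- w * (st$frac >= min_frac & st$log2fc > min_log2fc)
    l <- m[sample.int(t_n), lig_idx, drop = FALSE]
    r <- m[sample.int(t_n), rec_idx, drop = FALSE]
    as.vector(l %*% (pw$w_lr * t(r)))
  }

  null <- with_seed(cfg$seed, {
    if (cfg$exact_enumeration) {
      arr <- enumerate_label_arrangements(as.character(f))
      t(apply(arr, 1, function(a) one(factor(a, levels = levels(f)))))
    } else {
      t(vapply(seq_len(cfg$n_permutations), function(b) {
        if (cfg$null_scheme == "labels") one(sample(f)) else shuffle_edges()
      }, numeric(t_n * t_n)))
    }
  })
  types <- levels(f)
  structure(list(null = null,
                 pairs = data.frame(source = rep(types, times = t_n),
                                    target = rep(types, each = t_n),
                                    stringsAsFactors = FALSE),
                 types = types, exact = cfg$exact_enumeration),
            class = "comm_null")
}

#' Empirical p-values for observed connection weights
#'
#' One-sided enrichment p-values with the add-one correction:
#' `p = (1 + #\{null >= observed\}) / (B + 1)`, so p is never 0 and ties
#' count against the observation (conservative). With an exactly
#' enumerated null the p-value is the exact tail fraction
#' `#\{null >= observed\} / N` (the identity arrangement guarantees it
#' is positive). Adjusted p-values (Benjamini-Hochberg by default)
#' and strict significance calls (`padj < alpha_adj`) are attached.
#'
#' @param observed a [connection_weights] table.
#' @param nulls a [null_distribution] object.
#' @param adjust_method `"BH"` or `"bonferroni"`.
#' @param alpha_adj significance level on adjusted p-values.
#' @return data.frame of class `perm_result` with `source`, `target`,
#'   `weight`, `null_mean`, `null_sd`, `null_q95`, `n_null_ge` /
#'   `n_null_eq` (counts of null draws `>=` / `==` the observation, from
#'   which discreteness-aware randomized p-values can be formed for
#'   calibration diagnostics), `p`, `padj`, `significant`.
#' @export
empirical_pvalues <- function(observed, nulls, adjust_method = "BH",
                              alpha_adj = 0.01) {
  stopifnot(inherits(nulls, "comm_null"))
  b <- nrow(nulls$null)
  if (b == 0) stopf("empty null distribution")
  key_obs <- paste(observed$source, observed$target, sep = "\r")
  key_null <- paste(nulls$pairs$source, nulls$pairs$target, sep = "\r")
  idx <- match(key_null, key_obs)
  if (anyNA(idx))
    stopf("observed table lacks %d (source, target) pair(s)",
          sum(is.na(idx)))
  obs <- observed$weight[idx]
  ge <- colSums(nulls$null >= rep(obs, each = b))
  eq <- colSums(nulls$null == rep(obs, each = b))
  p <- if (nulls$exact) ge / b else (1 + ge) / (b + 1)
  res <- data.frame(source = nulls$pairs$source,
                    target = nulls$pairs$target, weight = obs,
                    null_mean = colMeans(nulls$null),
                    null_sd = apply(nulls$null, 2, sd),
                    null_q95 = apply(nulls$null, 2, quantile, 0.95),
                    n_null_ge = as.integer(ge), n_null_eq = as.integer(eq),
                    p = p,
                    padj = p.adjust(p, method = adjust_method),
                    stringsAsFactors = FALSE)
  res$significant <- res$padj < alpha_adj
  structure(res, class = c("perm_result", "data.frame"),
            n_permutations = b, adjust_method = adjust_method,
            alpha_adj = alpha_adj, types = nulls$types)
}

#' Apply a strict adjusted-p significance cutoff
#'
#' @param res a [empirical_pvalues] result (or any data.frame with a
#'   `padj` column).
#' @param alpha_adj cutoff; significant iff `padj < alpha_adj` (strict).
#' @return `res` with its `significant` column (re)computed.
#' @export
call_significant <- function(res, alpha_adj = 0.01) {
  if (nrow(res) == 0) {
    res$significant <- logical(0)
    return(res)
  }
  if (is.null(res$padj)) stopf("no 'padj' column present")
  res$significant <- res$padj < alpha_adj
  res
}

#' Full connection significance test
#'
#' Computes observed connection weights via the communication graph,
#' draws the permutation null, and returns empirical p-values with
#' multiple-testing adjustment and significance calls. Deterministic
#' given `cfg$seed`.
#'
#' @inheritParams null_distribution
#' @return A [empirical_pvalues] result, with the observed
#'   [connection_weights] table attached as attribute `"observed"` and
#'   the [build_communication_graph] object as attribute `"graph"`.
#' @export
test_connections <- function(nm, ca, lr, assoc,
                             cfg = permutation_config(),
                             min_frac = 0.10, min_log2fc = 0, eps = 1,
                             weight_type = "log2fc", min_cells = 3) {
  genes <- unique(c(lr$ligand_gene, lr$receptor_gene))
  genes <- intersect(genes, colnames(nm$values))
  fct <- compute_fold_changes(nm, ca, genes = genes, eps = eps,
                              min_cells = min_cells)
  g <- build_communication_graph(fct, lr, assoc, min_frac = min_frac,
                                 min_log2fc = min_log2fc,
                                 weight_type = weight_type)
  observed <- connection_weights(g)
  nulls <- null_distribution(nm, ca, lr, assoc, cfg = cfg,
                             min_frac = min_frac, min_log2fc = min_log2fc,
                             eps = eps, weight_type = weight_type,
                             min_cells = min_cells)
  res <- empirical_pvalues(observed, nulls,
                           adjust_method = cfg$adjust_method,
                           alpha_adj = cfg$alpha_adj)
  attr(res, "observed") <- observed
  attr(res, "graph") <- g
  res
}
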