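#' Pipeline configuration
#'
#' Collects input paths and every tunable parameter of the pipeline.
#' Defaults reproduce the standard analysis settings: QC filters
#' 200 / 6,500 / 40%, scale factor 1e6, 2,000 HVGs, 30 PCs, k = 20
#' neighbors, clustering resolution 1.5, fold-change pseudocount 1 CPM,
#' expression rule (frac >= 0.10, log2fc > 0), 100,000 permutations and
#' `padj < 0.01`.
#'
#' @param counts_dir 10x MatrixMarket directory (or `counts_tsv`).
#' @param counts_tsv dense TSV count matrix (alternative input).
#' @param labels_tsv optional precomputed labels; when given, clustering
#'   is skipped.
#' @param lr_tsv,assoc_tsv,alias_tsv knowledge tables (alias optional).
#' @param out_dir output directory.
#' @param min_genes,max_genes,max_mito_frac QC thresholds.
#' @param scale_factor,n_hvg,n_pcs,k_neighbors,snn_prune,resolution
#'   preprocessing parameters.
#' @param eps,min_frac,min_log2fc,weight_type communication-graph
#'   parameters.
#' @param n_permutations,alpha_adj,adjust_method,null_scheme permutation
#'   test parameters.
#' @param include_self include self connections in strength summaries.
#' @param seed master RNG seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(counts_dir = NULL, counts_tsv = NULL,
                            labels_tsv = NULL, lr_tsv, assoc_tsv,
                            alias_tsv = NULL, out_dir,
                            min_genes = 200, max_genes = 6500,
                            max_mito_frac = 0.40, scale_factor = 1e6,
                            n_hvg = 2000, n_pcs = 30, k_neighbors = 20,
                            snn_prune = 1 / 15, resolution = 1.5,
                            eps = 1, min_frac = 0.10, min_log2fc = 0,
                            weight_type = "log2fc",
                            n_permutations = 100000, alpha_adj = 0.01,
                            adjust_method = "BH", null_scheme = "labels",
                            include_self = FALSE, seed = 0) {
  if (is.null(counts_dir) && is.null(counts_tsv))
    stopf("one of 'counts_dir' or 'counts_tsv' is required")
  # range validation delegated to the stage constructors
  qc_thresholds(min_genes, max_genes, max_mito_frac)
  permutation_config(n_permutations, alpha_adj, seed,
                     null_scheme = null_scheme,
                     adjust_method = adjust_method)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full communication pipeline
#'
#' QC filter -> log-CPM normalization -> (clustering, unless labels are
#' supplied) -> ligand-receptor fold changes -> communication graph ->
#' connection weights -> permutation significance -> strength
#' summaries. All outputs are TSV files under `cfg$out_dir`, plus a
#' JSON run report with per-stage sizes, the parameter echo, collected
#' warnings, and an md5 manifest of every emitted file. Fully
#' deterministic given `cfg$seed`.
#'
#' @param cfg a [pipeline_config].
#' @return The run report (a list), invisibly; also written as
#'   `run_report.json`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  inputs <- c(counts_dir = cfg$counts_dir, counts_tsv = cfg$counts_tsv,
              labels_tsv = cfg$labels_tsv, lr_tsv = cfg$lr_tsv,
              assoc_tsv = cfg$assoc_tsv, alias_tsv = cfg$alias_tsv)
  for (nm_i in names(inputs))
    if (!file.exists(inputs[[nm_i]]))
      stopf("input path '%s' (%s) does not exist", inputs[[nm_i]], nm_i)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  warnings_log <- character(0)
  stages <- list()
  run_stage <- function(name, expr) {
    res <- withCallingHandlers(expr, warning = function(w) {
      warnings_log <<- c(warnings_log,
                         sprintf("[%s] %s", name, conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    message(sprintf("stage %-12s done", name))
    res
  }

  raw <- run_stage("read", {
    if (!is.null(cfg$counts_dir)) read_counts_10x(cfg$counts_dir)
    else read_counts_tsv(cfg$counts_tsv)
  })
  stages$read <- list(cells = nrow(raw$counts), genes = ncol(raw$counts))

  filtered <- run_stage("qc",
    qc_filter(raw, qc_thresholds(cfg$min_genes, cfg$max_genes,
                                 cfg$max_mito_frac)))
  stages$qc <- list(cells = nrow(filtered$counts),
                    genes = ncol(filtered$counts),
                    removed = nrow(raw$counts) - nrow(filtered$counts))

  nm <- run_stage("normalize", normalize_counts(filtered, cfg$scale_factor))

  ca <- run_stage("labels", {
    if (!is.null(cfg$labels_tsv)) {
      full <- read_labels_tsv(cfg$labels_tsv)
      missing <- setdiff(filtered$barcodes, names(full$labels))
      if (length(missing) > 0)
        stopf("labels file lacks %d post-QC barcode(s)", length(missing))
      cluster_assignment(full$labels[filtered$barcodes],
                         params = full$params)
    } else {
      hvg <- select_hvg(nm, n_top = cfg$n_hvg)
      scaled <- scale_and_regress(nm, genes = hvg)
      emb <- run_pca(scaled,
                     n_components = min(cfg$n_pcs, dim(scaled) - 1L))
      g <- build_neighbors(emb, k = min(cfg$k_neighbors,
                                        nrow(scaled) - 1L),
                           prune = cfg$snn_prune)
      cluster_graph(g, resolution = cfg$resolution, seed = cfg$seed)
    }
  })
  stages$labels <- list(cells = length(ca$labels),
                        types = length(unique(ca$labels)))

  kt <- run_stage("knowledge",
    read_knowledge_tables(cfg$lr_tsv, cfg$assoc_tsv, cfg$alias_tsv))
  stages$knowledge <- list(lr_pairs = nrow(kt$lr),
                           assoc_rows = nrow(kt$assoc),
                           duplicate_lr = kt$n_duplicate_lr,
                           unmapped_assoc = kt$n_unmapped_assoc)

  pcfg <- permutation_config(cfg$n_permutations, cfg$alpha_adj, cfg$seed,
                             null_scheme = cfg$null_scheme,
                             adjust_method = cfg$adjust_method)
  res <- run_stage("test",
    test_connections(nm, ca, kt$lr, kt$assoc, cfg = pcfg,
                     min_frac = cfg$min_frac,
                     min_log2fc = cfg$min_log2fc, eps = cfg$eps,
                     weight_type = cfg$weight_type))
  observed <- attr(res, "observed")
  stages$test <- list(connections = nrow(res),
                      significant = sum(res$significant))

  strengths <- run_stage("strengths", {
    list(all = node_strengths(res, include_self = cfg$include_self),
         significant = node_strengths(res, only_significant = TRUE,
                                      include_self = cfg$include_self))
  })

  g <- attr(res, "graph")

  outs <- c(labels = "labels.tsv", connections = "connections.tsv",
            strengths = "strengths.tsv",
            strengths_significant = "strengths_significant.tsv",
            edges = "edges.tsv", qc = "qc_summary.tsv")
  paths <- file.path(cfg$out_dir, outs)
  names(paths) <- names(outs)
  write_labels_tsv(ca, paths["labels"])
  conn_out <- merge(as.data.frame(res),
                    observed[, c("source", "target", "n_pairs", "self")],
                    by = c("source", "target"), sort = TRUE)
  write.table(conn_out, paths["connections"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(strengths$all, paths["strengths"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(strengths$significant, paths["strengths_significant"],
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as_edge_list(g), paths["edges"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(qc_metrics(raw), paths["qc"], sep = "\t", quote = FALSE,
              row.names = FALSE)

  pars <- cfg[!vapply(cfg, is.null, TRUE)]
  pars <- pars[order(names(pars))]
  pars <- pars[vapply(pars, function(x)
    is.numeric(x) || is.character(x) || is.logical(x), TRUE)]
  report <- list(
    stages = stages,
    parameters = pars,
    warnings = warnings_log,
    manifest = lapply(stats::setNames(as.vector(paths), basename(paths)),
                      function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(report, file.path(cfg$out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}
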