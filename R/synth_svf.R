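#' Planted ligand-receptor signal
#'
#' Ground-truth communication signal for the synthetic generator: the
#' ligand gene is overexpressed (`ligand_fold`) in the source cell type
#' and the receptor gene (`receptor_fold`) in the target type, and the
#' pair carries a protein-association score used when knowledge tables
#' are generated.
#'
#' @param ligand_gene,receptor_gene gene ids (must differ).
#' @param source_type,target_type cell-type labels.
#' @param ligand_fold,receptor_fold multiplicative effects >= 1 on the
#'   gene's negative-binomial mean within the stated type.
#' @param assoc_score integer association score in \[0, 1000\].
#' @return An object of class `planted_signal`.
#' @export
planted_signal <- function(ligand_gene, receptor_gene, source_type,
                           target_type, ligand_fold = 4, receptor_fold = 4,
                           assoc_score = 900) {
  if (!is.character(ligand_gene) || !is.character(receptor_gene))
    stopf("'ligand_gene' and 'receptor_gene' must be gene names")
  if (identical(ligand_gene, receptor_gene))
    stopf("'ligand_gene' must differ from 'receptor_gene'")
  assert_scalar_num(ligand_fold, "ligand_fold", min = 1)
  assert_scalar_num(receptor_fold, "receptor_fold", min = 1)
  assert_scalar_num(assoc_score, "assoc_score", min = 0, max = 1000,
                    integer = TRUE)
  structure(list(ligand_gene = ligand_gene, receptor_gene = receptor_gene,
                 source_type = as.character(source_type),
                 target_type = as.character(target_type),
                 ligand_fold = ligand_fold, receptor_fold = receptor_fold,
                 assoc_score = as.integer(assoc_score)),
            class = "planted_signal")
}

# Canonical mouse mitochondrial protein-coding gene names, used (in order)
# to name simulated mito genes so the "mt-" detection convention is real.
.mito_names <- c("mt-Nd1", "mt-Nd2", "mt-Co1", "mt-Co2", "mt-Atp8",
                 "mt-Atp6", "mt-Co3", "mt-Nd3", "mt-Nd4l", "mt-Nd4",
                 "mt-Nd5", "mt-Nd6", "mt-Cytb")

#' Specification of a synthetic SVF dataset
#'
#' Full parameterization of the negative-binomial stromal-vascular-
#' fraction simulator. Per-gene baseline means are log-normal
#' (`exp(N(baseline_log_mean, baseline_log_sd))`); counts for cell i of
#' type t at gene g are `NB(mean = libsize_i * base_g * fold(g, t),
#' size = nb_dispersion)` in the mean/size parameterization (`size` is
#' the inverse dispersion: variance = mean + mean^2/size). `fold(g, t)`
#' combines per-type marker-gene folds (which make types separable for
#' clustering) with the planted ligand/receptor folds. Library-size
#' factors are log-normal with unit mean and coefficient of variation
#' `libsize_cv`, so counts stay integer-valued NB draws rather than
#' post-hoc rescalings. A `qc_violator_fraction` of cells is rebuilt to
#' fail QC (detected genes truncated below 200, or mitochondrial counts
#' inflated above 40% of the cell total) so filter tests have planted
#' positives.
#'
#' @param n_cell_types number of cell types.
#' @param cells_per_type cells per type; scalar or vector of length
#'   `n_cell_types`.
#' @param n_genes total genes including mitochondrial genes.
#' @param baseline_log_mean,baseline_log_sd log-normal parameters of
#'   per-gene baseline means.
#' @param nb_dispersion shared NB size (inverse-dispersion) parameter.
#' @param libsize_cv coefficient of variation of per-cell library factors.
#' @param n_mito_genes number of mitochondrial genes (named `mt-*`).
#' @param mito_mean_frac expected fraction of a cell's counts that are
#'   mitochondrial, in \[0, 1).
#' @param markers_per_type,marker_fold number of exclusive marker genes
#'   per cell type and their fold change; set `markers_per_type = 0` for
#'   fully exchangeable (null) types.
#' @param planted_signals list of [planted_signal] objects.
#' @param qc_violator_fraction fraction of cells rebuilt to fail QC.
#' @param type_labels optional character labels; default `type1..typeK`.
#' @param seed integer seed; the seed fully determines the dataset.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_cell_types = 4, cells_per_type = 250,
                            n_genes = 500, baseline_log_mean = 0,
                            baseline_log_sd = 1, nb_dispersion = 2,
                            libsize_cv = 0.3, n_mito_genes = 13,
                            mito_mean_frac = 0.10, markers_per_type = 25,
                            marker_fold = 8, planted_signals = list(),
                            qc_violator_fraction = 0, type_labels = NULL,
                            seed = 0) {
  assert_scalar_num(n_cell_types, "n_cell_types", min = 1, integer = TRUE)
  if (!is.numeric(cells_per_type) ||
      !length(cells_per_type) %in% c(1L, n_cell_types) ||
      any(cells_per_type < 1) || any(cells_per_type != round(cells_per_type)))
    stopf("'cells_per_type' must be positive integer(s), length 1 or %d",
          n_cell_types)
  assert_scalar_num(n_genes, "n_genes", min = 1, integer = TRUE)
  assert_scalar_num(baseline_log_sd, "baseline_log_sd", min = 0)
  assert_scalar_num(nb_dispersion, "nb_dispersion", min = 0, strict_min = TRUE)
  assert_scalar_num(libsize_cv, "libsize_cv", min = 0)
  assert_scalar_num(n_mito_genes, "n_mito_genes", min = 0, integer = TRUE)
  if (n_mito_genes >= n_genes) stopf("'n_mito_genes' must be < n_genes")
  assert_scalar_num(mito_mean_frac, "mito_mean_frac", min = 0, max = 1,
                    strict_max = TRUE)
  assert_scalar_num(markers_per_type, "markers_per_type", min = 0,
                    integer = TRUE)
  assert_scalar_num(marker_fold, "marker_fold", min = 1)
  assert_scalar_num(qc_violator_fraction, "qc_violator_fraction", min = 0,
                    max = 1, strict_max = TRUE)
  assert_scalar_num(seed, "seed", integer = TRUE)
  if (is.null(type_labels)) type_labels <- paste0("type", seq_len(n_cell_types))
  if (length(type_labels) != n_cell_types || anyDuplicated(type_labels))
    stopf("'type_labels' must be %d unique labels", n_cell_types)
  if (!is.list(planted_signals) ||
      !all(vapply(planted_signals, inherits, TRUE, "planted_signal")))
    stopf("'planted_signals' must be a list of planted_signal objects")
  spec <- structure(
    list(n_cell_types = as.integer(n_cell_types),
         cells_per_type = as.integer(rep_len(cells_per_type, n_cell_types)),
         n_genes = as.integer(n_genes),
         baseline_log_mean = baseline_log_mean,
         baseline_log_sd = baseline_log_sd,
         nb_dispersion = nb_dispersion, libsize_cv = libsize_cv,
         n_mito_genes = as.integer(n_mito_genes),
         mito_mean_frac = mito_mean_frac,
         markers_per_type = as.integer(markers_per_type),
         marker_fold = marker_fold, planted_signals = planted_signals,
         qc_violator_fraction = qc_violator_fraction,
         type_labels = as.character(type_labels), seed = as.integer(seed)),
    class = "simulation_spec")
  validate_planted(spec)
  spec
}

gene_universe <- function(spec) {
  n_reg <- spec$n_genes - spec$n_mito_genes
  reg <- sprintf("g%04d", seq_len(n_reg))
  mito <- if (spec$n_mito_genes <= length(.mito_names))
    .mito_names[seq_len(spec$n_mito_genes)]
  else c(.mito_names, sprintf("mt-ext%d", seq_len(spec$n_mito_genes -
                                                    length(.mito_names))))
  c(reg, mito)
}

validate_planted <- function(spec) {
  genes <- gene_universe(spec)
  for (ps in spec$planted_signals) {
    for (f in c("ligand_gene", "receptor_gene"))
      if (!ps[[f]] %in% genes)
        stopf("planted signal %s '%s' is not in the simulated gene universe",
              f, ps[[f]])
    for (f in c("source_type", "target_type"))
      if (!ps[[f]] %in% spec$type_labels)
        stopf("planted signal %s '%s' is not a simulated cell-type label",
              f, ps[[f]])
  }
  invisible(spec)
}

# Marker genes per cell type: a reserved block at the top of the
# non-mito, non-planted gene range, assigned blockwise and disjointly.
# Deterministic by construction so knowledge-table decoys can avoid it.
marker_genes <- function(spec) {
  if (spec$markers_per_type == 0) return(NULL)
  genes <- gene_universe(spec)
  planted_genes <- unlist(lapply(spec$planted_signals, function(p)
    c(p$ligand_gene, p$receptor_gene)))
  pool <- setdiff(genes[seq_len(spec$n_genes - spec$n_mito_genes)],
                  planted_genes)
  need <- spec$markers_per_type * spec$n_cell_types
  if (length(pool) < need)
    stopf("not enough non-mito, non-planted genes for %d markers per type",
          spec$markers_per_type)
  chosen <- pool[length(pool) - need + seq_len(need)]
  split(chosen, rep(spec$type_labels, each = spec$markers_per_type))
}

# fold(g, t): per-type fold matrix combining marker and planted effects.
fold_matrix <- function(spec, genes) {
  K <- spec$n_cell_types
  fold <- matrix(1, K, spec$n_genes,
                 dimnames = list(spec$type_labels, genes))
  mk <- marker_genes(spec)
  for (t in names(mk)) fold[t, mk[[t]]] <- spec$marker_fold
  for (ps in spec$planted_signals) {
    fold[ps$source_type, ps$ligand_gene] <-
      fold[ps$source_type, ps$ligand_gene] * ps$ligand_fold
    fold[ps$target_type, ps$receptor_gene] <-
      fold[ps$target_type, ps$receptor_gene] * ps$receptor_fold
  }
  fold
}

#' Simulate a synthetic SVF scRNA-seq dataset
#'
#' Draws negative-binomial counts under the model documented in
#' [simulation_spec], flags mitochondrial genes, plants QC violators,
#' and returns the raw counts together with the true cell-type labels.
#' Output is fully determined by `spec$seed`.
#'
#' @param spec a [simulation_spec].
#' @return A list of class `svf_sim` with elements `counts`
#'   ([sc_counts]), `labels` ([cluster_assignment] of true types),
#'   `qc_violator` (named logical ground truth for planted violators),
#'   `base_means`, `fold` (types x genes fold matrix) and `spec`.
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  validate_planted(spec)
  genes <- gene_universe(spec)
  n_cells <- sum(spec$cells_per_type)
  labels <- rep(spec$type_labels, spec$cells_per_type)
  barcodes <- sprintf("cell%05d", seq_len(n_cells))

  with_seed(spec$seed, {
    n_reg <- spec$n_genes - spec$n_mito_genes
    base <- numeric(spec$n_genes)
    base[seq_len(n_reg)] <- rlnorm(n_reg, spec$baseline_log_mean,
                                   spec$baseline_log_sd)
    if (spec$n_mito_genes > 0) {
      # mito means scaled so the expected mito fraction is mito_mean_frac
      raw <- rlnorm(spec$n_mito_genes, 0, 0.5)
      target <- sum(base[seq_len(n_reg)]) *
        spec$mito_mean_frac / (1 - spec$mito_mean_frac)
      base[n_reg + seq_len(spec$n_mito_genes)] <- raw / sum(raw) * target
    }
    names(base) <- genes

    # marker genes get a common baseline so every type's marker block
    # carries the same expected library mass: per-type CPM composition
    # shifts then cancel and non-marker genes remain exchangeable
    mk <- marker_genes(spec)
    if (!is.null(mk))
      base[unlist(mk)] <- exp(spec$baseline_log_mean +
                                spec$baseline_log_sd^2 / 2)

    fold <- fold_matrix(spec, genes)

    libsize <- if (spec$libsize_cv > 0) {
      s2 <- log(1 + spec$libsize_cv^2)
      rlnorm(n_cells, -s2 / 2, sqrt(s2))
    } else rep(1, n_cells)

    counts <- matrix(0L, n_cells, spec$n_genes,
                     dimnames = list(barcodes, genes))
    offset <- 0L
    for (t in seq_len(spec$n_cell_types)) {
      nt <- spec$cells_per_type[t]
      rows <- offset + seq_len(nt)
      mu <- outer(libsize[rows], base * fold[t, ])
      counts[rows, ] <- rnbinom(length(mu), size = spec$nb_dispersion,
                                mu = mu)
      offset <- offset + nt
    }

    qc_violator <- rep(FALSE, n_cells)
    n_viol <- floor(spec$qc_violator_fraction * n_cells)
    if (n_viol > 0) {
      viol <- sort(sample.int(n_cells, n_viol))
      qc_violator[viol] <- TRUE
      mito_cols <- which(detect_mito(genes))
      for (j in seq_along(viol)) {
        i <- viol[j]
        if (j %% 2L == 1L || length(mito_cols) == 0L) {
          # low-complexity droplet: at most 150 detected genes (< 200)
          det <- which(counts[i, ] > 0)
          if (length(det) > 150)
            counts[i, sample(det, length(det) - 150L)] <- 0L
        } else {
          # mito-damaged cell: push mito content to ~60% of the total
          other <- sum(counts[i, -mito_cols])
          counts[i, mito_cols[1]] <- counts[i, mito_cols[1]] +
            as.integer(ceiling(1.5 * max(other, 10L)))
        }
      }
    }
    names(qc_violator) <- barcodes

    structure(
      list(counts = sc_counts(counts, barcodes, genes),
           labels = cluster_assignment(stats::setNames(labels, barcodes),
                                       params = list(source = "simulated")),
           qc_violator = qc_violator, base_means = base, fold = fold,
           spec = spec),
      class = "svf_sim")
  })
}

#' Simulate a null SVF dataset (exchangeable cell types)
#'
#' Runs [simulate_counts] with planted signals removed and marker folds
#' disabled, so no gene has a type-dependent mean: the cell types are
#' exchangeable and downstream connection p-values should be uniform.
#' Used to calibrate the permutation test.
#'
#' @param spec a [simulation_spec]; `planted_signals` and
#'   `markers_per_type` are overridden.
#' @return An `svf_sim` list, as from [simulate_counts].
#' @export
simulate_null_dataset <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  spec$planted_signals <- list()
  spec$markers_per_type <- 0L
  simulate_counts(spec)
}

#' Generate ligand-receptor and association-score tables
#'
#' Builds the two external knowledge tables that parameterize the
#' communication graph: a ligand-receptor pair table containing every
#' planted pair plus `n_decoys` random decoy pairs, and an association-
#' score table giving each planted pair its `assoc_score` and each decoy
#' the `decoy_score`. Decoy genes are drawn from the non-mitochondrial,
#' non-planted, non-marker gene universe, so decoy pairs carry no
#' type-enriched expression by construction. Deterministic given
#' `spec$seed`.
#'
#' @param spec a [simulation_spec].
#' @param n_decoys number of decoy pairs to add.
#' @param decoy_score association score for decoy pairs (default 400,
#'   i.e. STRING "medium confidence").
#' @return list with `lr` (data.frame `ligand_gene`, `receptor_gene`) and
#'   `assoc` (data.frame `gene_a`, `gene_b`, `combined_score`).
#' @export
make_knowledge_tables <- function(spec, n_decoys = 20, decoy_score = 400) {
  stopifnot(inherits(spec, "simulation_spec"))
  validate_planted(spec)
  assert_scalar_num(n_decoys, "n_decoys", min = 0, integer = TRUE)
  assert_scalar_num(decoy_score, "decoy_score", min = 0, max = 1000,
                    integer = TRUE)
  genes <- gene_universe(spec)
  lig <- vapply(spec$planted_signals, `[[`, "", "ligand_gene")
  rec <- vapply(spec$planted_signals, `[[`, "", "receptor_gene")
  score <- vapply(spec$planted_signals, `[[`, 0L, "assoc_score")
  with_seed(spec$seed + 99991L, {
    if (n_decoys > 0) {
      pool <- setdiff(genes[seq_len(spec$n_genes - spec$n_mito_genes)],
                      c(lig, rec, unlist(marker_genes(spec))))
      if (length(pool) < 2 * n_decoys)
        stopf("gene universe too small for %d decoy pairs", n_decoys)
      picked <- sample(pool, 2 * n_decoys)
      lig <- c(lig, picked[seq_len(n_decoys)])
      rec <- c(rec, picked[n_decoys + seq_len(n_decoys)])
      score <- c(score, rep(as.integer(decoy_score), n_decoys))
    }
    list(lr = data.frame(ligand_gene = lig, receptor_gene = rec,
                         stringsAsFactors = FALSE),
         assoc = data.frame(gene_a = lig, gene_b = rec,
                            combined_score = as.integer(score),
                            stringsAsFactors = FALSE))
  })
}
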