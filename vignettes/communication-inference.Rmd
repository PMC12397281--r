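---
title: "Inferring cell-cell communication from SVF single-cell RNA-seq"
author: "svfcomm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring cell-cell communication from SVF single-cell RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svfcomm)
```

## The problem

Adipose stromal vascular fraction (SVF) preparations are heterogeneous
mixtures of progenitors, immune and endothelial cells. After droplet
scRNA-seq and clustering, a recurring question is which cell types talk
to which: a *source* type secreting a ligand and a *target* type
expressing the corresponding receptor constitute a candidate
communication channel. `svfcomm` implements the complete chain from raw
counts to significant, direction-resolved cell-type connections, and
ships a synthetic SVF generator so every stage can be exercised and
validated without access to any external dataset.

## Preprocessing model

Cells are filtered with three strict thresholds: more than 200 detected
genes, fewer than 6,500 detected genes, and a mitochondrial count
fraction below 40%. The bounds are exclusive exactly as worded; a cell
sitting on a boundary is removed. Mitochondrial genes are recognized by
the `mt-`/`MT-` name prefix by default (an explicit flag vector can be
supplied instead, since annotation conventions vary).

Normalization is log-CPM with a scale factor of one million:

$$x_{ig} = \ln\!\left(\frac{c_{ig}}{\sum_g c_{ig}} \cdot 10^6 + 1\right)$$

so that for every cell with nonzero counts,
$\sum_g (e^{x_{ig}} - 1) = 10^6$ identically. Downstream code relies on
this invariant to move between log and linear scale; it is asserted in
the test suite for all nonzero cells.

Per-cell total read count is then regressed out of each gene as a
confounder (ordinary least squares with intercept) and residuals are
z-scored per gene; genes numerically fully explained by the covariate
map to zero columns. Highly variable genes are ranked by standardized
variance — gene variance divided by a mean-variance trend computed as
the mean variance within 20 equal-frequency bins of gene mean — with
lexicographic tie-breaking for determinism. We use a binned trend
rather than a loess fit because parity with any particular
implementation is not a goal and the binned estimator is transparent
and parameter-light. PCA (30 components by default) uses a fixed sign
convention (largest-magnitude loading positive). The neighbor graph is
a shared-nearest-neighbor graph: each cell's Euclidean k-NN set
(k = 20, the cell included, distance ties broken by index) is compared
by Jaccard overlap and edges below 1/15 are pruned. Communities are
found by Louvain modularity optimization at resolution 1.5, with
clusters labelled by decreasing size.

Defaults follow standard droplet practice: filters 200 / 6,500 / 40%,
scale factor $10^6$, 30 PCs, resolution 1.5 are the analysis settings;
k = 20, the 1/15 pruning, 2,000 HVGs and the 20-bin trend are common-
practice choices that are exposed in the configuration. Exact parity
with any specific clustering implementation is a non-goal; correctness
is assessed by recovery of planted structure (adjusted Rand index
against simulated types), not by cluster counts, which are data- and
version-dependent on real data.

Two points are deliberately left open by the upstream description and
resolved here as documented defaults: only total counts (not the
mitochondrial fraction) are regressed out, and datasets are processed
jointly; both behaviours are configurable.

## The communication graph

For each gene and cell type the fold change is computed on the linear
(CPM) scale against all other cells in the same dataset:

$$\mathrm{fc}(g, t) = \frac{\bar{e}_{g,t} + \varepsilon}
{\bar{e}_{g,\lnot t} + \varepsilon}, \qquad \varepsilon = 1\ \mathrm{CPM}$$

The pseudocount prevents division by zero and caps the fold change
when the out-group is pure drop-out (a gene seen only inside a type
with mean 9 CPM gets fc = 10, not infinity). A gene counts as
*expressed* by a type when at least 10% of its cells have a nonzero
count and $\log_2 \mathrm{fc} > 0$; both knobs are configurable, since
the underlying definition ("expression of a ligand") admits choices.

The communication graph links source type → ligand → receptor → target
type. Source-ligand and receptor-target edges are weighted by
$\max(\log_2 \mathrm{fc}, 0)$ — only enrichment drives communication;
raw fold change is available as a configuration alternative.
Ligand-receptor edges carry the protein-association combined score
scaled to $[0, 1]$ (score / 1000, the STRING convention); a pair absent
from the score table contributes nothing. The weight of an ordered
connection $(s, t)$ sums the three-edge products over all
ligand-receptor pairs with a complete path:

$$W(s,t) = \sum_{(l,r)} w_{sl}\, w_{lr}\, w_{rt}$$

Product combination along the path makes the association score act as
a confidence multiplier and lets a zero score annihilate a path; the
cross-pair aggregation is a sum. The upstream description states the
edge weightings but not the combination rule, so these are package
design choices, validated against a brute-force triple-loop oracle in
the tests. Per-type *outgoing* and *incoming* strengths are row and
column sums of $W$ over a selected connection set; self-connections
are computed and flagged but excluded from strength summaries by
default.

## Permutation significance

Significance of each ordered connection is assessed by network
permutation: cell-type labels are shuffled across cells (preserving
cluster sizes), fold changes are recomputed for the ligand/receptor
genes only (sufficient, because no other gene affects the graph), the
graph is rebuilt and all connection weights recorded. The default is
label permutation — the strictest null consistent with the graph's
inputs; an edge-shuffling null (permuting the type attachment of
source and target edges) is available behind a switch and is not the
default. The one-sided p-value uses the add-one rule

$$p = \frac{1 + \#\{W^{\mathrm{null}} \ge W^{\mathrm{obs}}\}}{B + 1}$$

so p is never zero and ties count against the observation
(conservative). At full scale $B = 100{,}000$; tests and the bundled
analyses use $B$ between 500 and 20,000 (sized so suites complete in
minutes), which is ample for the handful of connections tested here.
Adjustment is Benjamini-Hochberg across all tested ordered pairs per
network (Bonferroni available); the adjustment method behind the
upstream "Padj" is unstated, and BH is the conventional choice for
this family size. Significance is strict: $p_{\mathrm{adj}} < 0.01$.
Note the BH floor: with $m$ connections the smallest attainable
adjusted p is $m/(B+1)$, so detecting anything at $\alpha = 0.01$ with
16 connections requires $B \ge 1599$.

For tiny label multisets the complete set of distinct label
arrangements can be enumerated (`exact_enumeration`), giving exact
p-values against which the Monte-Carlo sampler is checked. Reported
p-values are deliberately conservative in the presence of ties; for
calibration diagnostics the result table exposes the `>=` and `==`
null counts from which the standard randomized (tie-broken) p-value —
exactly U(0,1) under label exchangeability — can be formed. The
calibration test uses that randomized form for its
Kolmogorov–Smirnov uniformity check, since the raw discrete p-values
are super-uniform by construction.

## The synthetic SVF generator

`simulate_counts()` draws counts for cell $i$ of type $t$ at gene $g$
from a negative binomial with mean
$\ell_i \cdot \beta_g \cdot \mathrm{fold}(g, t)$ and shared size
(inverse-dispersion) parameter, in the mean/size parameterization
(variance $= \mu + \mu^2/\mathrm{size}$) so the moment tests are
unambiguous. Baseline means $\beta_g$ are log-normal; library factors
$\ell_i$ are log-normal with unit mean and configurable CV, so counts
remain genuine integer NB draws rather than post-hoc rescalings.
Defaults (4 types, 500 genes, 13 `mt-` genes, dispersion size 2,
library CV 0.3, ~10% mitochondrial content, ~300 detected genes per
cell) mirror a small but realistic droplet SVF library; problem sizes
in the bundled analyses (2,000 cells) keep every stage interactive.

$\mathrm{fold}(g, t)$ combines three ingredients:

* **Marker blocks** make types separable for clustering tests: each
  type gets a disjoint block of marker genes (default 25 at fold 8).
  Marker genes share a common baseline mean so that every type's
  marker block carries the same expected library mass — otherwise the
  compositional nature of CPM would make *all* genes type-dependent
  and break the exchangeability that null calibration relies on.
* **Planted signals** overexpress a ligand in a source type and a
  receptor in a target type (`planted_signal`), the ground truth for
  recovery tests.
* **QC violators**: a configurable fraction of cells is rebuilt to
  fail the filters — detected genes truncated to at most 150, or
  mitochondrial counts inflated to ~60% of the cell — providing
  planted positives for filter tests.

`simulate_null_dataset()` disables both planted signals and markers,
so no gene has a type-dependent mean and the types are exchangeable:
downstream p-values must then be uniform, which is what the
calibration test checks (200 null datasets). `make_knowledge_tables()`
emits the planted pairs with their scores plus random decoy pairs
(default score 400 vs 900 for planted); decoys are drawn from
non-marker, non-planted genes so that "non-planted connection called
significant" is a genuine false positive.

What the generator does *not* emulate: gene-gene correlation beyond
the planted/marker structure, doublets, ambient RNA, batch effects,
or condition time-courses. Passing tests therefore demonstrate
algorithmic correctness and statistical calibration under a clean NB
model, not robustness to every artefact of real droplet data.

## Numerical conventions

* All tie-breaks are deterministic: ascending index for neighbor
  distances, lexicographic gene names for HVG ties, first occurrence
  for equal cluster sizes.
* Every random stage takes an explicit seed and restores the caller's
  RNG state; a fixed seed makes the full pipeline byte-deterministic
  (asserted via output checksums).
* Degenerate inputs are defined, not fatal: an empty post-QC matrix
  is a warning, an all-zero cell normalizes to an all-zero row,
  zero-variance genes scale to zero columns, rank-deficient PCA
  returns zero trailing components with a warning, and types with
  fewer than 3 cells are excluded from fold changes with a warning.
* MatrixMarket files are 1-based on disk (the standard), 0-based
  internally; a light structural validation reports header/entry
  mismatches with line numbers before parsing.

## Limitations

Connection-level inference only: per-pair p-values are intentionally
out of scope by default, as are ortholog mapping of ligand-receptor
maps, pathway-level aggregation, and cross-condition differential
communication testing (networks for different conditions are built
separately and compared descriptively). The fold-change baseline
(type vs all other cells within one dataset) is a documented default
where the upstream description is silent; per-condition analysis is
achieved by running the pipeline per condition.
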