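# svfcomm

Cell–cell communication inference for droplet single-cell RNA-seq of
adipose stromal vascular fraction (SVF) cells — and, generally, for any
clustered scRNA-seq dataset with a ligand–receptor map and
protein-association scores.

The package implements the full chain:

1. **Preprocessing** — strict QC filtering (more than 200 and fewer
   than 6,500 detected genes, mitochondrial fraction below 40%),
   log-CPM normalization (scale factor 10⁶), per-cell read-depth
   regression with per-gene z-scoring, highly-variable-gene selection,
   PCA (30 components), a shared-nearest-neighbor graph (k = 20,
   Jaccard pruning at 1/15), and Louvain clustering at resolution 1.5.
2. **Communication graph** — a weighted directed graph linking source
   cell types (expressing a ligand) to target cell types (expressing
   the corresponding receptor). Source→ligand and receptor→target
   edges are weighted by the clamped log₂ fold change of the gene in
   the type (`fc = (mean_in + 1)/(mean_out + 1)` on the CPM scale);
   ligand→receptor edges carry a protein-association combined score
   scaled to [0, 1]. The weight of an ordered connection (s, t) is

   W(s,t) = Σ over LR pairs of w_sl · w_lr · w_rt,

   and per-type incoming/outgoing strengths are column/row sums of W.
3. **Permutation significance** — cell-type labels are shuffled
   (preserving cluster sizes), the network is rebuilt each time, and
   each connection's one-sided p-value is
   `p = (1 + #{null ≥ observed}) / (B + 1)` (default B = 100,000 at
   full scale), Benjamini–Hochberg adjusted, significant iff
   `padj < 0.01` (strict).
4. **Synthetic SVF generator** — negative-binomial counts
   (mean/size parameterization) with log-normal baselines and library
   factors, per-type marker blocks, mitochondrial genes, planted QC
   violators and planted ligand–receptor signals, giving ground truth
   for every stage.

See `vignettes/communication-inference.Rmd` for the model, parameter
and calibration details.

## Worked example

The `analysis/` directory is a four-step workflow over a simulated
2,000-cell SVF dataset with one planted communication channel
(ligand `g0001` in `type1` → receptor `g0002` in `type2`, fold 4,
association score 900, among 10 decoy pairs):

```sh
Rscript analysis/01_simulate.R      # writes results/data
Rscript analysis/02_preprocess.R    # QC + clustering
Rscript analysis/03_network.R       # communication graph
Rscript analysis/04_significance.R  # permutation test
```

which prints (abridged):

```
simulated 2000 cells x 500 genes (100 planted QC violators)
QC kept 1898 cells (removed 102)
found 4 clusters at resolution 1.5
adjusted Rand index vs planted types: 1.000
strongest connections:
 source target     weight n_pairs
  type1  type2 3.57578965       5
  type2  type1 0.02948142       3
1 of 16 ordered connections significant at padj < 0.01
 source target  weight         p       padj
  type1  type2 3.57579 9.999e-05 0.00159984
```

Reading this: clustering exactly recovers the four simulated cell
types; the planted `type1 → type2` channel dominates the connection
matrix (weight ≈ 3.6 versus ≤ 0.03 elsewhere — the product of the
ligand's ~2 log₂ fold change, the 0.9 association weight and the
receptor's ~2 log₂ fold change); and the permutation test calls
exactly that one ordered connection significant, with the incoming
strength of `type2` and outgoing strength of `type1` equal to its
weight.

The same computation on real data runs through `run_pipeline()` with a
`pipeline_config()` pointing at a 10x-style MatrixMarket directory (or
dense TSV), optional precomputed labels, and the two knowledge tables
(ligand–receptor TSV; association-score TSV, optionally with a
protein→gene alias map).

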