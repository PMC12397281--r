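#!/usr/bin/env Rscript
# Build the weighted directed ligand-receptor communication graph
# between the planted cell types and summarize connection weights and
# per-type incoming/outgoing strengths (using the true labels, as when
# annotated cell types are supplied to the pipeline).

suppressPackageStartupMessages(library(svfcomm))

data_dir <- "results/data"
out_dir <- "results/network"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

raw <- read_counts_10x(file.path(data_dir, "counts"))
filtered <- qc_filter(raw)
nm <- normalize_counts(filtered)
labels <- read_labels_tsv(file.path(data_dir, "true_labels.tsv"))
ca <- cluster_assignment(labels$labels[filtered$barcodes])

kt <- read_knowledge_tables(file.path(data_dir, "lr_pairs.tsv"),
                            file.path(data_dir, "assoc_scores.tsv"))
lr_genes <- unique(c(kt$lr$ligand_gene, kt$lr$receptor_gene))
fct <- compute_fold_changes(nm, ca, genes = lr_genes)
g <- build_communication_graph(fct, kt$lr, kt$assoc)
ct <- connection_weights(g)
st <- node_strengths(ct)

cat(sprintf("graph over %d types and %d LR pairs\n",
            length(g$types), nrow(g$pairs)))
top <- ct[order(-ct$weight), ][1:3, ]
cat("strongest connections:\n")
print(top[, c("source", "target", "weight", "n_pairs")], row.names = FALSE)
cat(sprintf("total communication weight: %.3f\n", sum(ct$weight)))

write.table(ct, file.path(out_dir, "connections.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(st, file.path(out_dir, "strengths.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(as_edge_list(g), file.path(out_dir, "edges.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote", out_dir, "\n")
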