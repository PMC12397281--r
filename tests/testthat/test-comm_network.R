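test_that("fold changes follow the pseudocount formula", {
  # 3 types x 2 cells, gene means controlled exactly on the linear scale
  lin <- rbind(c(5, 4000, 9), c(5, 4000, 9),    # type A
               c(5, 2000, 0), c(5, 2000, 0),    # type B
               c(5, 2000, 0), c(5, 2000, 0))    # type C
  nm <- toy_norm(lin, genes = c("flat", "hi", "excl"))
  ca <- labels_for(nm, rep(c("A", "B", "C"), each = 2))
  fct <- compute_fold_changes(nm, ca, min_cells = 2)

  flat <- fct[fct$gene == "flat", ]
  expect_equal(flat$fc, rep(1, 3))
  expect_equal(flat$log2fc, rep(0, 3))

  hi_a <- fct[fct$gene == "hi" & fct$cell_type == "A", ]
  expect_equal(hi_a$fc, (4000 + 1) / (2000 + 1))
  expect_equal(hi_a$fc, 2, tolerance = 1e-3)
  expect_equal(hi_a$log2fc, log2((4000 + 1) / (2000 + 1)))

  # expressed only inside the type: mean_in 9, mean_out 0 -> fc = 10
  ex_a <- fct[fct$gene == "excl" & fct$cell_type == "A", ]
  expect_identical(ex_a$mean_out, 0)
  expect_equal(ex_a$fc, 10)
  expect_identical(ex_a$frac_expressing, 1)
  expect_identical(fct$frac_expressing[fct$gene == "excl" &
                                         fct$cell_type == "B"], 0)
})

test_that("types below the cell minimum are excluded with a warning", {
  lin <- matrix(10, 7, 2)
  nm <- toy_norm(lin)
  ca <- labels_for(nm, c(rep("A", 3), rep("B", 3), "tiny"))
  expect_warning(fct <- compute_fold_changes(nm, ca), "tiny")
  expect_setequal(unique(fct$cell_type), c("A", "B"))
})

test_that("the expression rule applies >= on fraction, > on log2fc", {
  fct <- structure(
    data.frame(gene = "L", cell_type = c("A", "B", "C", "D"),
               mean_in = 1, mean_out = 1,
               fc = c(4, 4, 1, 4), log2fc = c(2, 2, 0, 2),
               frac_expressing = c(0.5, 0, 0.5, 0.10)),
    class = c("fold_change_table", "data.frame"))
  expect_true(is_expressed(fct, "L", "A"))
  expect_false(is_expressed(fct, "L", "B"))     # zero expressing fraction
  expect_false(is_expressed(fct, "L", "C"))     # log2fc not > 0
  expect_true(is_expressed(fct, "L", "D"))      # boundary frac = 0.10
  expect_warning(miss <- is_expressed(fct, "L", "Z"), "no fold-change row")
  expect_false(miss)
})

make_fct <- function(rows) {
  structure(do.call(rbind, rows),
            class = c("fold_change_table", "data.frame"))
}
fct_row <- function(gene, type, log2fc, frac = 1) {
  fc <- 2^log2fc
  data.frame(gene = gene, cell_type = type, mean_in = fc, mean_out = 1,
             fc = fc, log2fc = log2fc, frac_expressing = frac,
             stringsAsFactors = FALSE)
}

test_that("a single complete path multiplies its three edge weights", {
  # ligand L: log2fc 2 in A only; receptor R: log2fc 3 in B only
  fct <- make_fct(list(
    fct_row("L", "A", 2), fct_row("L", "B", -1), fct_row("R", "A", -1),
    fct_row("R", "B", 3)))
  lr <- data.frame(ligand_gene = "L", receptor_gene = "R")
  assoc <- data.frame(gene_a = "L", gene_b = "R", combined_score = 900)
  g <- build_communication_graph(fct, lr, assoc)
  ct <- connection_weights(g)
  ab <- ct[ct$source == "A" & ct$target == "B", ]
  expect_equal(ab$weight, 2 * 0.9 * 3)
  expect_identical(ab$n_pairs, 1L)
  expect_true(all(ct$weight[!(ct$source == "A" & ct$target == "B")] == 0))

  # reversed score lookup works identically
  assoc_rev <- data.frame(gene_a = "R", gene_b = "L", combined_score = 900)
  g2 <- build_communication_graph(fct, lr, assoc_rev)
  expect_equal(connection_weights(g2)$weight, ct$weight)
})

test_that("degenerate graphs yield zero weights", {
  fct <- make_fct(list(fct_row("L", "A", 2), fct_row("L", "B", 1)))
  empty_lr <- data.frame(ligand_gene = character(),
                         receptor_gene = character())
  assoc <- data.frame(gene_a = character(), gene_b = character(),
                      combined_score = integer())
  g <- build_communication_graph(fct, empty_lr, assoc)
  ct <- connection_weights(g)
  expect_true(all(ct$weight == 0))
  expect_identical(nrow(ct), 4L)          # full ordered grid incl. self

  # ligand expressed nowhere: no source edges, no paths
  fct2 <- make_fct(list(
    fct_row("L", "A", -2), fct_row("L", "B", -2),
    fct_row("R", "A", 3), fct_row("R", "B", 3)))
  lr <- data.frame(ligand_gene = "L", receptor_gene = "R")
  assoc2 <- data.frame(gene_a = "L", gene_b = "R", combined_score = 900)
  ct2 <- connection_weights(build_communication_graph(fct2, lr, assoc2))
  expect_true(all(ct2$weight == 0))
  expect_true(all(ct2$n_pairs == 0L))
})

test_that("duplicate pairs collapse and multiple pairs sum", {
  fct <- make_fct(list(
    fct_row("L", "A", 2), fct_row("L", "B", -1),
    fct_row("R", "A", -1), fct_row("R", "B", 3),
    fct_row("L2", "A", 1), fct_row("L2", "B", -1),
    fct_row("R2", "A", -1), fct_row("R2", "B", 2)))
  lr <- data.frame(ligand_gene = c("L", "L", "L2"),
                   receptor_gene = c("R", "R", "R2"))
  assoc <- data.frame(gene_a = c("L", "L2"), gene_b = c("R", "R2"),
                      combined_score = c(900, 500))
  ct <- connection_weights(build_communication_graph(fct, lr, assoc))
  ab <- ct[ct$source == "A" & ct$target == "B", ]
  expect_equal(ab$weight, 2 * 0.9 * 3 + 1 * 0.5 * 2)
  expect_identical(ab$n_pairs, 2L)
})

test_that("a zero association score annihilates the pair", {
  fct <- make_fct(list(
    fct_row("L", "A", 5), fct_row("L", "B", -1),
    fct_row("R", "A", -1), fct_row("R", "B", 5)))
  lr <- data.frame(ligand_gene = "L", receptor_gene = "R")
  assoc0 <- data.frame(gene_a = "L", gene_b = "R", combined_score = 0)
  ct <- connection_weights(build_communication_graph(fct, lr, assoc0))
  expect_true(all(ct$weight == 0))
  # a pair absent from the table behaves the same, with a notice
  none <- data.frame(gene_a = character(), gene_b = character(),
                     combined_score = integer())
  expect_message(
    ct2 <- connection_weights(build_communication_graph(fct, lr, none)),
    "no association score")
  expect_true(all(ct2$weight == 0))
})

test_that("connection weights equal the brute-force triple loop", {
  for (s in 1:5) {
    n_types <- sample(2:6, 1)
    n_genes <- sample(6:16, 1)
    fct <- random_fct(n_types, n_genes, seed = 100 + s)
    genes <- unique(fct$gene)
    set.seed(200 + s)
    n_pairs <- sample(3:20, 1)
    lr <- data.frame(ligand_gene = sample(genes, n_pairs, replace = TRUE),
                     receptor_gene = sample(genes, n_pairs, replace = TRUE))
    keep <- sample(nrow(lr), max(1, nrow(lr) - 3))
    assoc <- data.frame(gene_a = lr$ligand_gene[keep],
                        gene_b = lr$receptor_gene[keep],
                        combined_score = sample(0:1000, length(keep)))
    oracle <- brute_force_weights(fct, lr, assoc)
    ct <- suppressMessages(connection_weights(
      build_communication_graph(fct, lr, assoc)))
    got <- matrix(ct$weight, n_types, n_types,
                  dimnames = list(sort(unique(fct$cell_type)),
                                  sort(unique(fct$cell_type))))
    expect_equal(got, oracle$weight, tolerance = 1e-12)
  }
})

test_that("increasing a single edge weight never lowers a connection", {
  fct <- random_fct(4, 8, seed = 7)
  genes <- unique(fct$gene)
  lr <- data.frame(ligand_gene = genes[1:4], receptor_gene = genes[5:8])
  assoc <- data.frame(gene_a = genes[1:4], gene_b = genes[5:8],
                      combined_score = c(300, 600, 900, 100))
  base_ct <- connection_weights(build_communication_graph(fct, lr, assoc))
  bumped <- fct
  i <- which(bumped$gene == genes[1] & bumped$log2fc > 0)[1]
  if (!is.na(i)) {
    bumped$log2fc[i] <- bumped$log2fc[i] + 1
    bumped$fc[i] <- 2^bumped$log2fc[i]
    new_ct <- connection_weights(build_communication_graph(bumped, lr,
                                                           assoc))
    expect_true(all(new_ct$weight >= base_ct$weight - 1e-12))
  }
})

test_that("node strengths sum rows and columns conservatively", {
  ct <- structure(
    data.frame(source = c("A", "B", "C"), target = c("B", "C", "A"),
               weight = c(2, 3, 4), n_pairs = 1L, self = FALSE),
    class = c("connection_table", "data.frame"),
    types = c("A", "B", "C"))
  st <- node_strengths(ct)
  expect_equal(st$outgoing[st$cell_type == "A"], 2)
  expect_equal(st$incoming[st$cell_type == "A"], 4)
  expect_equal(sum(st$incoming), 9)
  expect_equal(sum(st$outgoing), 9)

  # empty connection set -> all zeros
  none <- ct[0, ]
  attr(none, "types") <- c("A", "B", "C")
  st0 <- node_strengths(none)
  expect_true(all(st0$incoming == 0) && all(st0$outgoing == 0))

  # significance-restricted sums need the calls
  expect_error(node_strengths(ct, only_significant = TRUE), "significance")
  ct$significant <- c(TRUE, FALSE, TRUE)
  st_sig <- node_strengths(ct, only_significant = TRUE)
  expect_equal(sum(st_sig$incoming), 6)
  expect_equal(sum(st_sig$outgoing), 6)
})

test_that("the edge-list export carries provenance for every edge", {
  fct <- make_fct(list(
    fct_row("L", "A", 2), fct_row("L", "B", -1),
    fct_row("R", "A", -1), fct_row("R", "B", 3)))
  lr <- data.frame(ligand_gene = "L", receptor_gene = "R")
  assoc <- data.frame(gene_a = "L", gene_b = "R", combined_score = 900)
  el <- as_edge_list(build_communication_graph(fct, lr, assoc))
  expect_setequal(el$edge_type,
                  c("source_ligand", "ligand_receptor", "receptor_target"))
  expect_true(all(nzchar(el$provenance)))
  expect_equal(prod(el$weight), 2 * 0.9 * 3)
})
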