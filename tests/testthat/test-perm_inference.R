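test_that("label shuffles preserve the multiset and are uniform", {
  ca <- cluster_assignment(stats::setNames(c("A", "A", "B", "B"),
                                           paste0("c", 1:4)))
  # single label: shuffling is the identity
  one <- cluster_assignment(stats::setNames(rep("X", 5), paste0("c", 1:5)))
  expect_identical(permute_labels(one, seed = 1)$labels, one$labels)

  # multiset preservation, always
  for (s in 1:20)
    expect_identical(sort(table(permute_labels(ca, seed = s)$labels)),
                     sort(table(ca$labels)))

  # uniformity over the 6 distinct assignments of 2+2 labels
  n_rep <- 10000
  set.seed(99)
  keys <- replicate(n_rep, paste(sample(c("A", "A", "B", "B")),
                                 collapse = ""))
  freq <- table(keys) / n_rep
  expect_identical(length(freq), 6L)
  se <- sqrt((1 / 6) * (5 / 6) / n_rep)
  expect_true(all(abs(freq - 1 / 6) < 3 * se))
  # the package shuffler matches the direct oracle's support
  got <- unique(replicate(200, paste(permute_labels(ca)$labels,
                                     collapse = "")))
  expect_lte(length(got), 6L)
  expect_gte(length(got), 5L)
})

test_that("exhaustive label enumeration produces each arrangement once", {
  arr <- svfcomm:::enumerate_label_arrangements(c("A", "A", "B", "C"))
  expect_identical(nrow(arr), 12L)                 # 4!/2!
  expect_identical(anyDuplicated(apply(arr, 1, paste, collapse = "")), 0L)
  expect_error(
    svfcomm:::enumerate_label_arrangements(rep(c("A", "B"), 15)),
    "enumeration limit")
})

fake_null <- function(null_mat, types = c("A", "B")) {
  t_n <- length(types)
  structure(list(null = null_mat,
                 pairs = data.frame(source = rep(types, times = t_n),
                                    target = rep(types, each = t_n)),
                 types = types, exact = FALSE),
            class = "comm_null")
}
fake_observed <- function(w, types = c("A", "B")) {
  t_n <- length(types)
  data.frame(source = rep(types, times = t_n),
             target = rep(types, each = t_n), weight = w)
}

test_that("empirical p-values follow the add-one counting rule", {
  types <- c("A", "B")
  set.seed(5)
  null99 <- matrix(runif(99 * 4), 99, 4)
  # observation above every null draw: p = 1/100
  res <- empirical_pvalues(fake_observed(rep(2, 4)), fake_null(null99))
  expect_equal(res$p, rep(1 / 100, 4))

  # zero observation with non-negative nulls: p = 1
  res0 <- empirical_pvalues(fake_observed(rep(0, 4)), fake_null(null99))
  expect_equal(res0$p, rep(1, 4))

  # ties count toward the tail (>= rule)
  tied <- matrix(c(rep(0.5, 10), runif(10, 0, 0.4)), 20, 4)
  rest <- empirical_pvalues(fake_observed(rep(0.5, 4)), fake_null(tied))
  expect_equal(rest$p, rep((1 + 10) / 21, 4))
  expect_identical(rest$n_null_eq, rep(10L, 4))
})

test_that("BH adjustment and strict significance calls behave as stated", {
  # construct nulls so raw p = 0.01, 0.02, 0.03 (and 1) at B = 99
  types <- c("A", "B")
  null <- matrix(0, 99, 4)
  null[, 1] <- seq(0.001, 0.099, by = 0.001)
  null[, 2] <- null[, 1]; null[, 3] <- null[, 1]; null[, 4] <- null[, 1]
  obs <- c(1, 0.0985, 0.0975, -1)   # above all; above 98; above 97; none
  res <- empirical_pvalues(fake_observed(obs), fake_null(null))
  expect_equal(res$p, c(0.01, 0.02, 0.03, 1))
  expect_equal(res$padj[1:3], rep(0.03 * 4 / 3, 3))
  expect_equal(res$padj[4], 1)

  # single test: padj equals p
  res1 <- empirical_pvalues(
    data.frame(source = "A", target = "A", weight = 1),
    structure(list(null = matrix(runif(99), 99, 1),
                   pairs = data.frame(source = "A", target = "A"),
                   types = "A", exact = FALSE), class = "comm_null"))
  expect_equal(res1$padj, res1$p)

  # all p = 1 stays 1 after adjustment
  resu <- empirical_pvalues(fake_observed(rep(-1, 4)), fake_null(null))
  expect_true(all(resu$padj == 1))

  # strict cutoff: padj = 0.01 is NOT significant, 0.0099 is
  df <- data.frame(padj = c(0.01, 0.0099, 0.5))
  out <- call_significant(df, alpha_adj = 0.01)
  expect_identical(out$significant, c(FALSE, TRUE, FALSE))
  empty <- call_significant(df[0, , drop = FALSE])
  expect_identical(nrow(empty), 0L)
})

# A controlled 6-cell dataset with visible (but permutable) structure.
six_cell_nm <- function() {
  lin <- rbind(c(40, 2, 5, 5), c(30, 3, 5, 5),    # type A: ligand high
               c(4, 3, 5, 5), c(3, 2, 5, 5),      # type B
               c(2, 35, 5, 5), c(3, 28, 5, 5))    # type C: receptor high
  toy_norm(lin, genes = c("L", "R", "x1", "x2"))
}
six_cell_kt <- function() {
  list(lr = data.frame(ligand_gene = "L", receptor_gene = "R"),
       assoc = data.frame(gene_a = "L", gene_b = "R",
                          combined_score = 800))
}

test_that("Monte-Carlo p-values converge to the exact enumeration", {
  nm <- six_cell_nm()
  ca <- labels_for(nm, c("A", "A", "B", "B", "C", "C"))
  kt <- six_cell_kt()
  exact <- test_connections(nm, ca, kt$lr, kt$assoc,
                            cfg = permutation_config(
                              exact_enumeration = TRUE, seed = 1),
                            min_cells = 2)
  # 6! / (2! 2! 2!) = 90 distinct arrangements
  expect_identical(attr(exact, "n_permutations"), 90L)
  b <- 2000
  mc <- test_connections(nm, ca, kt$lr, kt$assoc,
                         cfg = permutation_config(n_permutations = b,
                                                  seed = 2),
                         min_cells = 2)
  for (i in seq_len(nrow(exact))) {
    se <- sqrt(exact$p[i] * (1 - exact$p[i]) / b)
    expect_lt(abs(mc$p[i] - exact$p[i]), 3 * se + 2 / b)
  }
})

test_that("a ligand flat across cells contributes nothing in any permutation", {
  lin <- cbind(rep(7, 6), c(30, 25, 2, 3, 2, 3), matrix(5, 6, 2))
  nm <- toy_norm(lin, genes = c("L", "R", "x1", "x2"))
  ca <- labels_for(nm, c("A", "A", "B", "B", "C", "C"))
  kt <- six_cell_kt()
  nulls <- null_distribution(nm, ca, kt$lr, kt$assoc,
                             cfg = permutation_config(n_permutations = 300,
                                                      seed = 3),
                             min_cells = 2)
  # fc ~ 1 up to floating point, so clamped log2fc and paths are ~0
  expect_true(all(nulls$null < 1e-10))
  obs <- connection_weights(build_communication_graph(
    compute_fold_changes(nm, ca, genes = c("L", "R"), min_cells = 2),
    kt$lr, kt$assoc))
  expect_true(all(obs$weight < 1e-10))
})

test_that("the full test is deterministic and capacity-guarded", {
  nm <- six_cell_nm()
  ca <- labels_for(nm, c("A", "A", "B", "B", "C", "C"))
  kt <- six_cell_kt()
  r1 <- test_connections(nm, ca, kt$lr, kt$assoc,
                         cfg = permutation_config(n_permutations = 100,
                                                  seed = 11),
                         min_cells = 2)
  r2 <- test_connections(nm, ca, kt$lr, kt$assoc,
                         cfg = permutation_config(n_permutations = 100,
                                                  seed = 11),
                         min_cells = 2)
  expect_identical(as.data.frame(r1), as.data.frame(r2))

  expect_error(
    null_distribution(nm, ca, kt$lr, kt$assoc,
                      cfg = permutation_config(n_permutations = 100,
                                               budget = 10),
                      min_cells = 2),
    "reduce n_permutations")
})

test_that("the alternative edge-shuffling null runs and is calibrated in size", {
  nm <- six_cell_nm()
  ca <- labels_for(nm, c("A", "A", "B", "B", "C", "C"))
  kt <- six_cell_kt()
  res <- test_connections(nm, ca, kt$lr, kt$assoc,
                          cfg = permutation_config(
                            n_permutations = 200, seed = 5,
                            null_scheme = "edge_shuffle"),
                          min_cells = 2)
  expect_true(all(res$p > 0 & res$p <= 1))
})
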