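# The synthetic study system: knowledge graphs, counts, continuous states,
# normalization.

test_that("scenario validation rejects non-positive settings", {
  expect_error(synthetic_scenario(n_genes = 0), "positive")
  expect_error(synthetic_scenario(dispersion = 0), "positive")
  expect_error(make_knowledge(synthetic_scenario(n_genes = 30, n_tfs = 20,
                                                 n_cell_types = 5,
                                                 marker_genes_per_type = 5)),
               "too small")
})

test_that("knowledge graphs have the designed record counts and planting", {
  sc <- synthetic_scenario(n_genes = 200, n_tfs = 8, n_terms = 10,
                           genes_per_term = 5, targets_per_tf = 6,
                           n_cell_types = 3, marker_genes_per_type = 4,
                           seed = 21)
  kn <- make_knowledge(sc)
  ann <- kn$annotations
  # planted terms: markers + the TF's own gene; random terms: genes_per_term
  sizes <- table(ann$go_term)
  planted <- vapply(kn$planted_truth, `[[`, "", "go_term")
  expect_true(all(sizes[planted] == 4 + 1))
  expect_true(all(sizes[setdiff(names(sizes), planted)] == 5))
  for (tr in kn$planted_truth) {
    expect_true(all(tr$markers %in% ann$gene[ann$go_term == tr$go_term]))
    regulon <- kn$tf_targets$target[kn$tf_targets$tf == tr$tf]
    expect_true(all(tr$markers %in% regulon))
  }
  # marker sets disjoint across types
  all_markers <- unlist(lapply(kn$planted_truth, `[[`, "markers"))
  expect_false(anyDuplicated(all_markers) > 0)
  # determinism
  kn2 <- make_knowledge(sc)
  expect_identical(kn, kn2)
  kn3 <- make_knowledge(synthetic_scenario(n_genes = 200, n_tfs = 8,
                                           n_terms = 10, genes_per_term = 5,
                                           targets_per_tf = 6,
                                           n_cell_types = 3,
                                           marker_genes_per_type = 4,
                                           seed = 22))
  expect_false(identical(kn$annotations, kn3$annotations))
})

test_that("simulated counts have the right shape and are reproducible", {
  sc <- tiny_scenario(seed = 13)
  kn <- make_knowledge(sc)
  cells <- simulate_cells(sc, kn)
  expect_identical(dim(cells$counts),
                   c(sc$n_cell_types * sc$n_cells_per_type, sc$n_genes))
  expect_identical(cells$counts, simulate_cells(sc, kn)$counts)
  expect_true(all(cells$counts >= 0))
  expect_true(all(cells$counts == round(cells$counts)))
  expect_identical(table(cells$labels)[[1]], sc$n_cells_per_type)
})

test_that("effect_size 0 leaves markers at baseline; effect_size 2 lifts them e^2-fold", {
  sc0 <- synthetic_scenario(n_genes = 300, n_cell_types = 3,
                            n_cells_per_type = 200, effect_size = 0,
                            seed = 17)
  kn0 <- make_knowledge(sc0)
  cells0 <- simulate_cells(sc0, kn0)
  mk <- kn0$planted_truth$type1$markers
  in_type <- cells0$labels == "type1"
  m_marker <- mean(cells0$counts[in_type, mk])
  nonmark <- setdiff(colnames(cells0$counts),
                     unlist(lapply(kn0$planted_truth, `[[`, "markers")))
  m_other <- mean(cells0$counts[in_type, nonmark])
  se <- stats::sd(cells0$counts[in_type, mk]) / sqrt(sum(in_type) * length(mk))
  expect_lt(abs(m_marker - m_other), 3 * se + 3 * se)

  sc2 <- synthetic_scenario(n_genes = 300, n_cell_types = 3,
                            n_cells_per_type = 200, effect_size = 2,
                            seed = 18)
  kn2 <- make_knowledge(sc2)
  cells2 <- simulate_cells(sc2, kn2)
  mk2 <- kn2$planted_truth$type1$markers
  fold <- mean(cells2$counts[cells2$labels == "type1", mk2]) /
    mean(cells2$counts[cells2$labels != "type1", mk2])
  expect_lt(abs(fold - exp(2)) / exp(2), 0.2)
})

test_that("continuous scores live in [0,1] and drive their programs", {
  sc <- synthetic_scenario(n_genes = 300, n_cell_types = 5,
                           n_cells_per_type = 100, seed = 19)
  kn <- make_knowledge(sc)
  cont <- simulate_continuous(sc, kn)
  expect_true(all(cont$scores >= 0 & cont$scores <= 1))
  expect_length(cont$scores, 500L)
  expect_length(cont$up_program, sc$program_genes)
  expect_length(intersect(cont$up_program, cont$down_program), 0L)
  # up-program genes correlate positively, down-program negatively
  up_r <- mean(apply(cont$counts[, cont$up_program], 2,
                     stats::cor, y = cont$scores))
  down_r <- mean(apply(cont$counts[, cont$down_program], 2,
                       stats::cor, y = cont$scores))
  expect_gt(up_r, 0.2)
  expect_lt(down_r, -0.1)
  expect_identical(cont$counts, simulate_continuous(sc, kn)$counts)
})

test_that("effect_size 0 decouples continuous scores from all genes", {
  sc <- synthetic_scenario(n_genes = 300, n_cell_types = 5,
                           n_cells_per_type = 100, effect_size = 0,
                           seed = 23)
  kn <- make_knowledge(sc)
  cont <- simulate_continuous(sc, kn)
  rs <- apply(cont$counts, 2, stats::cor, y = cont$scores)
  expect_gt(mean(abs(rs) < 0.1), 0.95)
})

test_that("log-normalization follows the per-cell depth convention", {
  counts <- rbind(c(10, 0), c(5, 5))
  em <- lognormalize(counts)
  expect_equal(unname(em$values[1, ]), c(log1p(10000), 0), tolerance = 1e-12)
  expect_equal(unname(em$values[2, ]), rep(log1p(5000), 2), tolerance = 1e-12)
  # sequencing-depth invariance: doubling all counts changes nothing
  em2 <- lognormalize(counts * 2)
  expect_equal(em$values, em2$values, ignore_attr = TRUE)
  expect_error(lognormalize(matrix(0, 2, 2)), "zero total")
  expect_warning(em3 <- lognormalize(rbind(c(1, 1), c(0, 0))), "dropped")
  expect_equal(nrow(em3$values), 1L)
  expect_error(lognormalize(matrix(-1, 1, 2)), "non-negative")
})

test_that("expression_matrix enforces unique genes and non-negative values", {
  expect_error(expression_matrix(matrix(1, 2, 2),
                                 gene_names = c("a", "a")), "unique")
  expect_error(expression_matrix(matrix(-1, 1, 2),
                                 gene_names = c("a", "b")), "non-negative")
  em <- expression_matrix(matrix(1, 2, 2), gene_names = c("a", "b"))
  expect_identical(dim(em), c(2L, 2L))
})
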