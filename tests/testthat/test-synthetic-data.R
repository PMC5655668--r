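test_that("gene expression aggregates isoform FPKM additively", {
  cells <- c("a", "b")
  # one gene, single isoform: gene matrix identical to isoform matrix
  iso1 <- matrix(c(1.5, 3.2), 1, 2, dimnames = list("g1.t1", cells))
  e1 <- expression_dataset(iso1, data.frame(isoform_id = "g1.t1",
                                            gene_id = "g1"),
                           c(a = "lung", b = "lung"))
  expect_equal(unname(e1$gene_matrix[1, ]), unname(iso1[1, ]))

  # all-zero FPKM isoforms give zero gene expression
  iso0 <- matrix(0, 3, 2, dimnames = list(paste0("g1.t", 1:3), cells))
  map0 <- data.frame(isoform_id = rownames(iso0), gene_id = "g1")
  expect_true(all(aggregate_isoforms(iso0, map0) == 0))

  # FPKM 3 and 1 combine to log2(1 + 3 + 1)
  iso2 <- matrix(log2(c(3, 1) + 1), 2, 1,
                 dimnames = list(c("g1.t1", "g1.t2"), "a"))
  map2 <- data.frame(isoform_id = rownames(iso2), gene_id = "g1")
  expect_equal(unname(aggregate_isoforms(iso2, map2)[1, 1]), log2(5))
})

test_that("the gene matrix is always recomputable from the isoform matrix", {
  for (seed in 1:5) {
    expr <- simulate_expression(simulation_config(
      n_cell_lines = 30, n_genes = 25, seed = seed))
    expect_equal(expr$gene_matrix,
                 aggregate_isoforms(expr$isoform_matrix,
                                    expr$isoform_map))
  }
})

test_that("identical configs give bit-identical studies", {
  cfg <- simulation_config(n_cell_lines = 40, n_genes = 20,
                           planted_effects = data.frame(
                             gene = 1, beta = 0.5, mode = "gene_level"),
                           seed = 77)
  expect_identical(simulate_study(cfg), simulate_study(cfg))
  other <- simulate_study(simulation_config(n_cell_lines = 40,
                                            n_genes = 20, seed = 78))
  expect_false(identical(simulate_study(cfg)$expression$isoform_matrix,
                         other$expression$isoform_matrix))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_cell_lines = 0))
  expect_error(simulation_config(n_cell_lines = 2, n_tissues = 5))
  expect_error(simulation_config(inter_study_rho = 1.2))
  expect_error(simulation_config(
    planted_effects = data.frame(gene = 1, beta = Inf,
                                 mode = "gene_level")))
  expect_error(simulation_config(
    planted_effects = data.frame(gene = 7, beta = 1, mode = "gene_level"),
    n_genes = 5))
  # planted feature missing from the expression dataset handed in
  cfg <- simulation_config(n_genes = 10, planted_effects = data.frame(
    gene = 9, beta = 0.5, mode = "gene_level"))
  small <- simulate_expression(simulation_config(n_genes = 3))
  expect_error(simulate_sensitivity(small, cfg), "unknown planted feature")
})

test_that("sensitivity respects its limiting cases", {
  # no effects, no noise: AAC constant within tissue
  cfg <- simulation_config(n_cell_lines = 30, n_tissues = 3, n_genes = 5,
                           noise_sd = 0, seed = 3)
  expr <- simulate_expression(cfg)
  sens <- simulate_sensitivity(expr, cfg)
  by_tissue <- split(sens$aac, expr$tissues[sens$cell_line])
  expect_true(all(vapply(by_tissue, function(a) diff(range(a)) == 0,
                         logical(1))))

  # perfect inter-study correlation: the two AAC vectors are identical
  cfg1 <- simulation_config(n_cell_lines = 50, n_genes = 5,
                            inter_study_rho = 1, seed = 4)
  st <- simulate_study(cfg1)
  a <- split(st$sensitivity$aac, st$sensitivity$study_id)
  expect_identical(a$study1, a$study2)
})

test_that("inter-study Spearman correlation is calibrated to target", {
  sp <- vapply(1:50, function(seed) {
    cfg <- simulation_config(n_cell_lines = 200, n_tissues = 4,
                             n_genes = 10,
                             planted_effects = data.frame(
                               gene = 1, beta = 0.8, mode = "gene_level"),
                             inter_study_rho = 0.5, seed = seed)
    st <- simulate_study(cfg)
    a <- split(st$sensitivity$aac, st$sensitivity$study_id)
    cor(a$study1, a$study2, method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(sp) - 0.5), 0.1)
})

test_that("isoform-specific signal is diluted by gene-level aggregation", {
  d <- vapply(1:20, function(seed) {
    cfg <- simulation_config(n_cell_lines = 80, n_tissues = 1,
                             n_genes = 10,
                             planted_effects = data.frame(
                               gene = 1, beta = 0.8,
                               mode = "isoform_specific"),
                             noise_sd = 0.3, seed = seed)
    expr <- simulate_expression(cfg)
    sens <- simulate_sensitivity(expr, cfg)
    aac <- sens$aac[match(colnames(expr$isoform_matrix), sens$cell_line)]
    abs(cor(expr$isoform_matrix["g0001.t1", ], aac)) -
      abs(cor(expr$gene_matrix["g0001", ], aac))
  }, numeric(1))
  expect_gt(mean(d), 0)
})

test_that("simulated plates reproduce the generating curve", {
  doses <- 10^seq(-2, 2, length.out = 9)
  pars <- list(ec50 = 1, slope = 1, e_inf = 0)
  # zero replicate noise: normalized viabilities sit exactly on the curve
  pl <- simulate_plates(pars, doses, replicate_cv = 0)
  norm <- preprocess_srb(pl)
  curve <- pars$e_inf + (1 - pars$e_inf) / (1 + doses / pars$ec50)
  expect_equal(colMeans(norm$viabilities), curve, tolerance = 1e-12)

  # EC50 far below the lowest dose with a steep slope: everything dead
  pl2 <- simulate_plates(list(ec50 = 1e-4, slope = 5, e_inf = 0), doses,
                         replicate_cv = 0)
  expect_true(all(preprocess_srb(pl2)$viabilities < 1e-3))

  # mid-grid parameters: pipeline AAC close to the analytic value
  got <- summarize_plate(simulate_plates(pars, doses,
                                         replicate_cv = 0.02))$aac
  f <- function(x) pmin(1, pmax(0, 1 / (1 + 10^x / pars$ec50)))
  analytic <- 1 - integrate(f, -2, 2, rel.tol = 1e-10)$value / 4
  expect_lt(abs(got - analytic), 0.02)

  expect_error(simulate_plates(pars, c(1, 1, 2)), "increasing")
})
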