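make_validation_pair <- function(seed, beta = 0.8, n_val = 70) {
  pe <- data.frame(gene = 1, beta = beta, mode = "gene_level")
  train <- simulation_config(n_cell_lines = 100, n_tissues = 4,
                             n_genes = 20, planted_effects = pe,
                             noise_sd = 0.3, seed = seed)
  val <- simulation_config(n_cell_lines = n_val, n_tissues = 4,
                           n_genes = 20, planted_effects = pe,
                           noise_sd = 0.3, seed = seed + 5000)
  list(train = simulate_study(train, study_ids = "train"),
       val = simulate_study(val, study_ids = "validation"))
}

test_that("the display effect is the signed concordance excess", {
  expect_equal(effect_display(0.75, 2.3), 0.25)
  expect_equal(effect_display(0.75, -0.4), -0.25)
  expect_equal(effect_display(0.5, -7), 0)
  expect_equal(effect_display(0.8, 0), 0)
  expect_error(effect_display(1.2, 1))
})

test_that("an opposite-sign association is never validated", {
  pair <- make_validation_pair(3)
  cand <- data.frame(feature_id = "g0001", level = "gene",
                     gene_id = "g0001", drug = "drug1",
                     sign_train = -1, beta_train = -0.8)
  out <- validate_biomarkers(cand, pair$val$expression,
                             pair$val$sensitivity)
  expect_lt(out$p_validation, 0.05)       # strongly significant ...
  expect_false(out$validated)             # ... but the sign disagrees
})

test_that("a replicated planted signal validates", {
  pair <- make_validation_pair(4)
  cand <- data.frame(feature_id = "g0001", level = "gene",
                     gene_id = "g0001", drug = "drug1",
                     sign_train = 1, beta_train = 0.8)
  out <- validate_biomarkers(cand, pair$val$expression,
                             pair$val$sensitivity)
  expect_true(out$validated)
  expect_equal(out$status, "tested")
})

test_that("validation is monotone in alpha and symmetric under negation", {
  pair <- make_validation_pair(6, beta = 0.25)
  cand <- data.frame(feature_id = sprintf("g%04d", 1:10), level = "gene",
                     gene_id = sprintf("g%04d", 1:10), drug = "drug1",
                     sign_train = 1, beta_train = 0.5)
  loose <- validate_biomarkers(cand, pair$val$expression,
                               pair$val$sensitivity,
                               validation_rule(alpha = 0.05))
  strict <- validate_biomarkers(cand, pair$val$expression,
                                pair$val$sensitivity,
                                validation_rule(alpha = 0.01))
  expect_true(all(which(strict$validated) %in% which(loose$validated)))

  # negating expression everywhere and flipping the training signs leaves
  # the outcome unchanged
  neg <- pair$val$expression
  neg$gene_matrix <- -neg$gene_matrix
  neg$isoform_matrix <- -neg$isoform_matrix
  cand_neg <- cand
  cand_neg$sign_train <- -cand$sign_train
  out <- validate_biomarkers(cand, pair$val$expression,
                             pair$val$sensitivity)
  out_neg <- validate_biomarkers(cand_neg, neg, pair$val$sensitivity)
  expect_equal(out$validated, out_neg$validated)
  expect_equal(out$p_validation, out_neg$p_validation, tolerance = 1e-10)
})

test_that("missing features and absent drugs are reported explicitly", {
  pair <- make_validation_pair(7)
  cand <- data.frame(feature_id = c("g0001", "not_a_feature"),
                     level = "gene", gene_id = c("g0001", "gX"),
                     drug = "drug1", sign_train = 1, beta_train = 0.5)
  out <- validate_biomarkers(cand, pair$val$expression,
                             pair$val$sensitivity)
  expect_equal(out$status, c("tested", "missing_feature"))
  expect_true(is.na(out$validated[2]))

  cand$drug <- "absent_drug"
  expect_error(validate_biomarkers(cand, pair$val$expression,
                                   pair$val$sensitivity), "not testable")
})

test_that("tissue pre-selection keeps planted signal and drops noise", {
  cfg <- simulation_config(n_cell_lines = 160, n_tissues = 2,
                           n_genes = 20,
                           planted_effects = data.frame(
                             gene = 1, beta = 0.9, mode = "gene_level"),
                           noise_sd = 0.3, seed = 12)
  st <- simulate_study(cfg, study_ids = "train")
  cand <- data.frame(feature_id = c("g0001", "g0002"), level = "gene",
                     gene_id = c("g0001", "g0002"), drug = "drug1",
                     sign_train = 1, beta_train = c(0.9, 0))
  kept <- preselect_tissue(cand, st$expression, st$sensitivity, "drug1",
                           tissue = "tissue01", n_min = 20,
                           plan = bootstrap_plan(50, 1))
  expect_true("g0001" %in% kept$feature_id)   # planted signal survives
  expect_false("g0002" %in% kept$feature_id)  # noise feature near 0.5

  # empty candidate set: empty output, no error
  empty <- preselect_tissue(cand[0, ], st$expression, st$sensitivity,
                            "drug1", tissue = "tissue01")
  expect_equal(nrow(empty), 0)

  # too few cell lines of the tissue: empty with a warning
  expect_warning(
    out <- preselect_tissue(cand, st$expression, st$sensitivity, "drug1",
                            tissue = "tissue01", n_min = 1000),
    "cell lines")
  expect_equal(nrow(out), 0)
})

test_that("sibling isoform correlations are reported against the candidate", {
  cfg <- simulation_config(n_cell_lines = 60, n_genes = 5,
                           isoform_probs = c(0, 0, 1), seed = 2)
  expr <- simulate_expression(cfg)
  tab <- isoform_correlations(expr, "g0001.t2")
  expect_equal(tab$isoform_id[1], "g0001.t2")
  expect_equal(tab$correlation[1], 1)
  expect_equal(nrow(tab), 3)
  expect_error(isoform_correlations(expr, "nope"), "unknown")
})
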