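make_signal_study <- function(seed, n = 100, beta = 0.8) {
  cfg <- simulation_config(
    n_cell_lines = n, n_tissues = 4, n_genes = 10,
    planted_effects = data.frame(gene = 1, beta = beta,
                                 mode = "gene_level"),
    noise_sd = 0.3, seed = seed)
  expr <- simulate_expression(cfg)
  list(expr = expr, sens = simulate_sensitivity(expr, cfg))
}

test_that("bootstrap vectors are reproducible and sized by the plan", {
  st <- make_signal_study(1, n = 40)
  plan <- bootstrap_plan(n_boot = 2, seed = 5)
  a <- bootstrap_ci(st$expr, st$sens, "drug1", "g0001", "gene",
                    plan = plan)
  b <- bootstrap_ci(st$expr, st$sens, "drug1", "g0001", "gene",
                    plan = plan)
  expect_length(a$ci_vector, 2)
  expect_length(a$null_ci_vector, 2)
  expect_identical(a, b)
  c2 <- bootstrap_ci(st$expr, st$sens, "drug1", "g0001", "gene",
                     plan = bootstrap_plan(n_boot = 2, seed = 6))
  expect_false(identical(a, c2))
})

test_that("a noise feature scores near-chance out-of-bag concordance", {
  # single tissue, so the prediction carries the expression term alone
  meds <- vapply(1:20, function(seed) {
    cfg <- simulation_config(n_cell_lines = 100, n_tissues = 1,
                             n_genes = 10, noise_sd = 0.3, seed = seed)
    expr <- simulate_expression(cfg)
    sens <- simulate_sensitivity(expr, cfg)
    median(bootstrap_ci(expr, sens, "drug1", "g0002", "gene",
                        plan = bootstrap_plan(50, seed))$ci_vector,
           na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(meds) - 0.5), 0.05)
})

test_that("a strong planted effect scores high concordance", {
  meds <- vapply(1:20, function(seed) {
    st <- make_signal_study(seed)
    median(bootstrap_ci(st$expr, st$sens, "drug1", "g0001", "gene",
                        plan = bootstrap_plan(50, seed))$ci_vector,
           na.rm = TRUE)
  }, numeric(1))
  expect_gte(mean(meds > 0.55), 0.95)
})

test_that("signed-rank test matches exact enumeration and extremes", {
  # strict dominance in all 100 pairs
  expect_lt(signed_rank_test(seq(0.6, 0.8, length.out = 100),
                             seq(0.4, 0.55, length.out = 100),
                             "greater")$p_value, 1e-15)
  # identical vectors: no evidence
  expect_equal(signed_rank_test(rep(0.5, 10), rep(0.5, 10),
                                "greater")$p_value, 1)
  # hand-enumerated small sample with midranks for tied |differences|:
  # diffs (0.1, 0.15, 0.15), all positive, W+ = 6, P(W+ >= 6) = 1/8
  sr <- signed_rank_test(c(0.6, 0.7, 0.65), c(0.5, 0.55, 0.5), "greater")
  expect_equal(sr$statistic, 6)
  expect_equal(sr$p_value, 1 / 8)
  # agreement with the reference exact test on tie-free data
  set.seed(21)
  for (i in 1:20) {
    x <- rnorm(10)
    y <- rnorm(10)
    ref <- wilcox.test(x, y, paired = TRUE, alternative = "greater",
                       exact = TRUE)
    got <- signed_rank_test(x, y, "greater")
    expect_equal(got$p_value, unname(ref$p.value))
    expect_equal(got$statistic, unname(ref$statistic))
  }
})

test_that("model comparison is invariant to joint pair permutation", {
  set.seed(31)
  ci_m <- runif(40, 0.4, 0.9)
  ci_0 <- runif(40, 0.4, 0.6)
  p1 <- compare_models(ci_m, ci_0)$p_vs_null
  perm <- sample(40)
  p2 <- compare_models(ci_m[perm], ci_0[perm])$p_vs_null
  expect_equal(p1, p2)
  # too few pairs is not evaluable
  expect_true(is.na(compare_models(ci_m[1:5], ci_0[1:5])$p_vs_null))
  expect_equal(compare_models(ci_m[1:5], ci_0[1:5], min_pairs = 3)$p_vs_null,
               signed_rank_test(ci_m[1:5], ci_0[1:5], "greater")$p_value)
})

test_that("meta-combination is a sample-size-weighted mean", {
  expect_equal(meta_combine(list(beta = 0.4, p = 0.2, n = 50),
                            list(beta = 0.6, p = 0.2, n = 50))$beta, 0.5)
  m <- meta_combine(list(beta = 0.3, p = 0.01, n = 100),
                    list(beta = 0.3, p = 0.04, n = 50))
  expect_equal(m$p, 0.02)
  # identical studies: meta equals either one
  one <- list(beta = -0.25, p = 0.007, n = 80)
  m2 <- meta_combine(one, one)
  expect_equal(m2$beta, one$beta)
  expect_equal(m2$p, one$p)
  # symmetry and reduction to identity at n2 = 0
  a <- list(beta = 0.5, p = 0.02, n = 70)
  b <- list(beta = -0.1, p = 0.6, n = 30)
  expect_equal(meta_combine(a, b)[c("beta", "p")],
               meta_combine(b, a)[c("beta", "p")])
  m3 <- meta_combine(a, list(beta = 1, p = 0.5, n = 0))
  expect_equal(m3$beta, a$beta)
  expect_true(m3$single_study)
  expect_true(meta_combine(a, list(beta = -0.5, p = 0.02,
                                   n = 30))$sign_disagreement)
})

test_that("the FDR step matches a reference step-up computation", {
  recs <- data.frame(
    gene_id = paste0("g", 1:4), best_isoform_id = paste0("g", 1:4, ".t1"),
    drug = "d", meta_beta_gene = 0.5,
    meta_p_gene = c(0.001, 0.008, 0.039, 0.041),
    meta_beta_isoform = 0.5, meta_p_isoform = c(0.02, 0.5, 0.9, 1),
    ci_gene = 0.7, ci_isoform = 0.7, p_wilcox_gene = 1e-4,
    p_wilcox_isoform = 1e-4)
  called <- call_biomarkers(recs, fdr_threshold = 0.05)
  expect_equal(called$fdr_gene, c(0.004, 0.016, 0.041, 0.041))
  # best isoform p = 0.02 adjusts to 0.08 under BH, above the cutoff
  expect_equal(called$fdr_isoform[1], 0.08)
  expect_equal(called$category[1], "gene_specific")
  # property check against the step-up oracle on random vectors
  set.seed(13)
  for (len in c(10, 100, 1000)) {
    p <- runif(len)^2
    expect_equal(p.adjust(p, "BH"), bh_stepup(p))
  }
})

test_that("missing concordance or test values fail the calling gate", {
  recs <- data.frame(
    gene_id = "g1", best_isoform_id = "g1.t1", drug = "d",
    meta_beta_gene = 0.5, meta_p_gene = 1e-6,
    meta_beta_isoform = 0.5, meta_p_isoform = 1e-6,
    ci_gene = NA_real_, ci_isoform = 0.7,
    p_wilcox_gene = 1e-4, p_wilcox_isoform = NA_real_)
  called <- call_biomarkers(recs)
  expect_false(called$significant_gene)
  expect_false(called$significant_isoform)
  expect_equal(called$category, "none")
})

test_that("under a global null the typical concordance stays near chance", {
  meds <- vapply(1:50, function(seed) {
    cfg <- simulation_config(n_cell_lines = 60, n_tissues = 1,
                             n_genes = 5, noise_sd = 0.3, seed = seed)
    expr <- simulate_expression(cfg)
    sens <- simulate_sensitivity(expr, cfg, drug = "drug1")
    median(bootstrap_ci(expr, sens, "drug1", "g0001", "gene",
                        plan = bootstrap_plan(40, seed))$ci_vector,
           na.rm = TRUE)
  }, numeric(1))
  expect_gte(median(meds), 0.45)
  expect_lte(median(meds), 0.55)
})
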