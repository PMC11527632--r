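test_that("cohort spec validates its ranges", {
  expect_error(cohort_spec(prop_state_B = 1.2), "prop_state_B")
  expect_error(cohort_spec(censor_rate = 1), "censor_rate")
  expect_error(cohort_spec(n_signature_genes = 50, n_genes = 40), "exceeds")
  expect_error(cohort_spec(effect_size = NaN), "non-finite")
  expect_error(cohort_spec(batch_scale = 0), "positive")
})

test_that("fixed seed gives bit-identical cohorts", {
  a <- generate_bulk_cohort(cohort_spec(n_samples = 40, n_genes = 60, seed = 9))
  b <- generate_bulk_cohort(cohort_spec(n_samples = 40, n_genes = 60, seed = 9))
  expect_identical(a$expression$values, b$expression$values)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth, b$truth)
})

test_that("delta = 0 leaves signature genes at the nominal false-positive rate", {
  coh <- generate_bulk_cohort(cohort_spec(n_samples = 200, n_genes = 300,
                                          effect_size = 0, n_batches = 1,
                                          batch_shift = 0, batch_scale = 1,
                                          seed = 3))
  st <- coh$truth$latent_state
  p <- apply(coh$expression$values[coh$truth$signature_gene_ids, ], 1,
             function(x) t.test(x[st == "A"], x[st == "B"])$p.value)
  expect_lt(mean(p < 0.05), 0.25)  # 23 genes: wide binomial band around 0.05
  # across all genes the rate is tight around the nominal level
  p_all <- apply(coh$expression$values, 1,
                 function(x) t.test(x[st == "A"], x[st == "B"])$p.value)
  expect_lt(abs(mean(p_all < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 300))
})

test_that("delta = 2 states are recoverable by direct k-means", {
  coh <- generate_bulk_cohort(cohort_spec(n_samples = 200, n_genes = 300,
                                          effect_size = 2, n_batches = 1,
                                          batch_shift = 0, batch_scale = 1,
                                          seed = 4))
  X <- t(coh$expression$values[coh$truth$signature_gene_ids, ])
  set.seed(1)
  km <- kmeans(scale(X), centers = 2, nstart = 10)
  ari <- mclust::adjustedRandIndex(km$cluster, coh$truth$latent_state)
  expect_gte(ari, 0.9)
})

test_that("background genes carry no latent-state signal", {
  coh <- small_cohort(seed = 5)
  bg <- setdiff(rownames(coh$expression$values), coh$truth$signature_gene_ids)
  slopes <- apply(coh$expression$values[bg, ], 1, function(x)
    coef(lm(x ~ coh$truth$latent_score))[2])
  expect_lt(abs(mean(slopes)), 0.05)
})

test_that("censoring rate lands near its target", {
  coh <- generate_bulk_cohort(cohort_spec(n_samples = 500, censor_rate = 0.3,
                                          seed = 6))
  expect_lt(abs(mean(1 - coh$clinical$event) - 0.3), 0.07)
  full <- generate_bulk_cohort(cohort_spec(n_samples = 100, censor_rate = 0,
                                           seed = 6))
  expect_true(all(full$clinical$event == 1))
})

test_that("mutation counts track the latent score as configured", {
  spec0 <- cohort_spec(n_samples = 500, n_genes = 50, tmb_beta = 0, seed = 7)
  coh0 <- generate_bulk_cohort(spec0)
  maf0 <- generate_mutation_table(spec0, coh0$truth)
  r0 <- cor(attr(maf0, "nonsyn_counts"), coh0$truth$latent_score)
  expect_lt(abs(r0), 0.1)

  spec1 <- cohort_spec(n_samples = 500, n_genes = 50, tmb_beta = -0.6, seed = 7)
  maf1 <- generate_mutation_table(spec1, coh0$truth)
  ct <- cor.test(attr(maf1, "nonsyn_counts"), coh0$truth$latent_score)
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.05)

  # degenerate limit: log-mean -Inf gives an empty table
  maf_empty <- generate_mutation_table(spec1, coh0$truth, tmb_alpha = -Inf)
  expect_equal(nrow(maf_empty), 0L)
  expect_true(all(attr(maf_empty, "nonsyn_counts") == 0))
})

test_that("single-cell generator enriches the requested type", {
  props <- c(tcell = 0.3, bcell = 0.3, tumor = 0.4)
  mod <- paste0("MOD", 1:20)
  null_cm <- generate_single_cell(400, 500, props, mod, "tcell", seed = 8,
                                  enrichment = 1, qc_violation_frac = 0)
  norm0 <- normalize_log1p(null_cm)
  ms0 <- module_score(norm0, mod, seed = 1)
  means0 <- tapply(ms0$score, null_cm$cell_type, mean)
  expect_lt(diff(range(means0)), 3 * sd(ms0$score) / sqrt(100))

  enr <- generate_single_cell(400, 500, props, mod, "tcell", seed = 8,
                              enrichment = 4, qc_violation_frac = 0)
  ms1 <- module_score(normalize_log1p(enr), mod, seed = 1)
  means1 <- tapply(ms1$score, enr$cell_type, mean)
  expect_equal(names(which.max(means1)), "tcell")
})

test_that("planted QC violations are counted within binomial error", {
  cm <- generate_single_cell(1000, 600, c(a = 0.5, b = 0.5), paste0("MOD", 1:10),
                             "a", seed = 9, qc_violation_frac = 0.1)
  filtered <- qc_filter(cm)
  n_removed <- attr(filtered, "n_removed")
  expect_lt(abs(n_removed - 100), 3 * sqrt(1000 * 0.1 * 0.9))
})
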