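fixture_expr <- function(n_genes = 10, n_samples = 20, seed = 41) {
  set.seed(seed)
  make_expr(matrix(rnorm(n_genes * n_samples, mean = 4), n_genes))
}

test_that("loadings reproduce an independent SVD up to sign", {
  m <- fixture_expr()
  model <- fit_score_model(m, rownames(m$values))
  X <- m$values
  Z <- (X - rowMeans(X)) / sqrt(rowSums((X - rowMeans(X))^2) / ncol(X))
  sv <- svd(Z)
  for (comp in 1:2) {
    l <- if (comp == 1) model$loadings1 else model$loadings2
    ref <- sv$u[, comp]
    expect_equal(abs(sum(l * ref)), 1, tolerance = 1e-8)  # colinear unit vectors
  }
  expect_lt(abs(sum(model$loadings1 * model$loadings2)), 1e-8)
  expect_equal(sum(model$loadings1^2), 1, tolerance = 1e-12)
})

test_that("duplicating every sample leaves loadings unchanged", {
  m <- fixture_expr()
  m2 <- make_expr(cbind(m$values, m$values),
                  genes = rownames(m$values),
                  samples = sprintf("d%02d", 1:40))
  a <- fit_score_model(m, rownames(m$values))
  b <- fit_score_model(m2, rownames(m2$values))
  expect_equal(a$loadings1, b$loadings1, tolerance = 1e-8)
  expect_equal(a$loadings2, b$loadings2, tolerance = 1e-8)
})

test_that("scoring is centered, linear and constant-shift invariant", {
  m <- fixture_expr()
  model <- fit_score_model(m, rownames(m$values))
  sc <- score_samples(model, m)
  # training cohort scores are centered projections
  expect_lt(abs(mean(sc$tlsscore)), 1e-8)
  expect_equal(sc$tlsscore, sc$pc1 - sc$pc2)

  # a sample at the training mean of every gene scores 0
  m_mean <- make_expr(matrix(model$gene_means, ncol = 1),
                      genes = model$gene_ids, samples = "avg")
  expect_lt(abs(score_samples(model, m_mean)$tlsscore), 1e-12)

  # linearity: score of an averaged sample is the average of scores
  v <- (m$values[, 1] + m$values[, 2]) / 2
  m_avg <- make_expr(matrix(v, ncol = 1), genes = model$gene_ids,
                     samples = "mix")
  expect_equal(score_samples(model, m_avg)$tlsscore,
               mean(sc$tlsscore[1:2]), tolerance = 1e-10)

  # adding a gene-wise constant to the cohort does not move the scores
  shifted <- make_expr(m$values + rnorm(nrow(m$values)),
                       genes = rownames(m$values),
                       samples = colnames(m$values))
  model_s <- fit_score_model(shifted, rownames(m$values))
  expect_equal(score_samples(model_s, shifted)$tlsscore, sc$tlsscore,
               tolerance = 1e-8)
})

test_that("rank-1 structure concentrates the score on component 1", {
  set.seed(42)
  block <- outer(rep(1, 8), rnorm(30, sd = 4))
  X <- block + matrix(rnorm(8 * 30, sd = 0.05), 8)
  m <- make_expr(X + 5)
  model <- fit_score_model(m, rownames(m$values))
  expect_lt(model$sdev[2] / model$sdev[1], 0.05)
  sc <- score_samples(model, m)
  expect_gt(abs(cor(sc$tlsscore, sc$pc1)), 0.999)
})

test_that("missing model genes error unless imputation is requested", {
  m <- fixture_expr()
  model <- fit_score_model(m, rownames(m$values))
  m_drop <- subset_expression(m, genes = rownames(m$values)[-1])
  expect_error(score_samples(model, m_drop), "missing")
  expect_warning(sc <- score_samples(model, m_drop, impute_missing = TRUE),
                 "imputed")
  expect_true(all(is.finite(sc$tlsscore)))
})

test_that("synthetic cohorts score along the latent axis and dichotomize", {
  coh <- generate_bulk_cohort(cohort_spec(n_samples = 300, n_genes = 400,
                                          n_batches = 1, batch_shift = 0,
                                          batch_scale = 1, seed = 43))
  m <- coh$expression
  sig <- coh$truth$signature_gene_ids
  # favorable block: genes elevated in the protective (lower-hazard) B state
  fav <- names(coh$truth$signature_shift)[coh$truth$signature_shift > 0]
  model <- fit_score_model(m, sig, favorable_genes = fav)
  sc <- score_samples(model, m)
  r <- cor(sc$tlsscore, coh$truth$latent_score)
  expect_gte(abs(r), 0.8)

  di <- dichotomize(sc, coh$clinical)
  expect_lt(attr(di, "logrank")$p, 0.01)
  expect_true(all((di$tlsscore > di$cutpoint) == (di$group == "high")))

  # determinism
  di2 <- dichotomize(score_samples(model, m), coh$clinical)
  expect_identical(di$cutpoint[1], di2$cutpoint[1])

  # constant score cannot be dichotomized
  sc0 <- sc; sc0$tlsscore <- 1
  expect_error(dichotomize(sc0, coh$clinical), "candidate")
})

test_that("widening the state separation never shrinks the score gap", {
  gaps <- vapply(c(0, 1, 2, 4), function(delta) {
    coh <- generate_bulk_cohort(cohort_spec(n_samples = 150, n_genes = 150,
                                            effect_size = delta,
                                            n_batches = 1, batch_shift = 0,
                                            batch_scale = 1, seed = 44))
    model <- fit_score_model(coh$expression, coh$truth$signature_gene_ids)
    sc <- score_samples(model, coh$expression)
    st <- coh$truth$latent_state
    abs(mean(sc$tlsscore[st == "B"]) - mean(sc$tlsscore[st == "A"]))
  }, numeric(1))
  expect_true(all(diff(gaps) > -0.2))
  expect_gt(gaps[4], gaps[1])
})

test_that("score-TMB strata combine the two splits and report correlations", {
  spec <- cohort_spec(n_samples = 500, n_genes = 300, n_batches = 1,
                      batch_shift = 0, batch_scale = 1, tmb_beta = -0.6,
                      seed = 45)
  coh <- generate_bulk_cohort(spec)
  maf <- generate_mutation_table(spec, coh$truth)
  tmb <- tmb_from_maf(maf, samples = coh$clinical$sample_id)
  model <- fit_score_model(coh$expression, coh$truth$signature_gene_ids)
  di <- dichotomize(score_samples(model, coh$expression), coh$clinical)
  strata <- score_tmb_strata(di, tmb, coh$clinical)
  expect_setequal(unique(strata$tmb_group), c("high", "low"))
  expect_equal(length(unique(strata$stratum)), 4L)
  pear <- attr(strata, "pearson")
  expect_lt(pear$r, 0)
  expect_lt(pear$p, 0.05)
  expect_error(score_tmb_strata(di, setNames(rep(1, nrow(di)), di$sample_id),
                                coh$clinical), "equal")
})
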