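test_that("kaplan-meier matches hand product-limit calculations", {
  km <- kaplan_meier(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$survival, c(0.75, 0.50, 0.25, 0))
  expect_equal(km$at_risk, c(4L, 3L, 2L, 1L))

  # all censored: no event times, S stays 1 everywhere
  km0 <- kaplan_meier(c(1, 2, 3), c(0, 0, 0))
  expect_length(km0$times, 0)
  expect_equal(km_survival_at(km0, c(0, 5)), c(1, 1))

  # censor at 2: risk sets (4, 2, 1), S = 0.75, 0.375, 0
  km1 <- kaplan_meier(c(1, 2, 3, 4), c(1, 0, 1, 1))
  expect_equal(km1$times, c(1, 3, 4))
  expect_equal(km1$at_risk, c(4L, 2L, 1L))
  expect_equal(km1$survival, c(0.75, 0.375, 0))
  expect_equal(km_survival_at(km1, c(1, 2, 3, 4)), c(0.75, 0.75, 0.375, 0))
  expect_error(kaplan_meier(numeric(0), numeric(0)), "empty")
})

test_that("kaplan-meier equals the empirical survival without censoring and
           matches the reference implementation with it", {
  set.seed(31)
  t_ev <- rexp(40)
  km <- kaplan_meier(t_ev, rep(1, 40))
  emp <- vapply(km$times, function(tt) mean(t_ev > tt), numeric(1))
  expect_equal(km$survival, emp, tolerance = 1e-12)

  ev <- rbinom(40, 1, 0.6)
  km2 <- kaplan_meier(t_ev, ev)
  sf <- survival::survfit(survival::Surv(t_ev, ev) ~ 1)
  ref <- summary(sf, times = km2$times)$surv
  expect_equal(km2$survival, ref, tolerance = 1e-10)
})

test_that("log-rank matches hand-unrolled O-E sums and the reference", {
  # duplicated identical groups: no separation at all
  tm <- c(1, 2, 3, 1, 2, 3); ev <- rep(1, 6); g <- rep(c("x", "y"), each = 3)
  lr0 <- logrank_test(tm, ev, g)
  expect_equal(lr0$chi2, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)

  # A events at 1,2; B at 10,11 - hand-unrolled tables:
  # t=1: n=4 nA=2 d=1 -> E_A=1/2, V=1*(1/2)(1/2)=1/4
  # t=2: n=3 nA=1 d=1 -> E_A=1/3, V=1*(1/3)(2/3)=2/9
  # t=10,11: nA=0, no contribution
  tm2 <- c(1, 2, 10, 11); g2 <- c("A", "A", "B", "B")
  lr <- logrank_test(tm2, rep(1, 4), g2)
  chi2_hand <- (2 - (1 / 2 + 1 / 3))^2 / (1 / 4 + 2 / 9)
  expect_equal(lr$chi2, chi2_hand, tolerance = 1e-12)
  ref <- survival::survdiff(survival::Surv(tm2, rep(1, 4)) ~ g2)
  expect_equal(lr$chi2, ref$chisq, tolerance = 1e-10)

  # symmetry under label swap
  lr_swap <- logrank_test(tm2, rep(1, 4), rev(g2)[c(3, 4, 1, 2)])
  expect_equal(lr_swap$chi2, lr$chi2)
  expect_error(logrank_test(tm2, rep(1, 4), rep("A", 4)), "2 non-empty")
})

test_that("log-rank handles k > 2 groups against the reference", {
  set.seed(32)
  tm <- rexp(60); ev <- rbinom(60, 1, 0.7); g <- sample(letters[1:3], 60, TRUE)
  lr <- logrank_test(tm, ev, g)
  ref <- survival::survdiff(survival::Surv(tm, ev) ~ g)
  expect_equal(lr$chi2, ref$chisq, tolerance = 1e-8)
  expect_equal(lr$df, 2L)
})

test_that("cox fit maximizes the partial likelihood (grid oracle)", {
  tm <- c(1, 2, 3, 4); ev <- rep(1, 4); x <- c(1, 0, 1, 0)
  fit <- cox_fit(tm, ev, matrix(x, ncol = 1, dimnames = list(NULL, "x")))
  # no ties: write out the partial likelihood and grid-search it
  pl <- function(b) {
    risk <- list(1:4, 2:4, 3:4, 4)
    sum(vapply(1:4, function(i)
      x[i] * b - log(sum(exp(x[risk[[i]]] * b))), numeric(1)))
  }
  grid <- seq(-5, 5, by = 1e-4)
  b_star <- grid[which.max(vapply(grid, pl, numeric(1)))]
  expect_equal(fit$beta, b_star, tolerance = 1e-4)
})

test_that("cox fit reproduces the reference Efron fit with ties", {
  set.seed(33)
  n <- 80
  x <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4))
  tm <- round(rexp(n, exp(0.5 * x[, 1])), 1) + 0.1  # induce ties
  ev <- rbinom(n, 1, 0.75)
  fit <- cox_fit(tm, ev, x)
  ref <- survival::coxph(survival::Surv(tm, ev) ~ x, ties = "efron")
  expect_equal(fit$beta, unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$se, unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
})

test_that("cox fit handles degenerate inputs as contracted", {
  tm <- c(1, 2, 3, 4, 1, 2, 3, 4); ev <- rep(1, 8)
  # duplicated identical groups: no effect
  x <- rep(c(0, 1), each = 4)
  fit <- cox_fit(tm, ev, matrix(c(x), ncol = 1))
  expect_equal(fit$hr, 1, tolerance = 1e-6)

  expect_error(cox_fit(tm, ev, matrix(1, 8, 1, dimnames = list(NULL, "z"))),
               "constant covariate")
  expect_error(cox_fit(tm, rep(0, 8), matrix(rnorm(8), ncol = 1)),
               "at least one event")

  # perfect separation: capped and flagged
  sep <- c(1, 1, 1, 1, 0, 0, 0, 0)
  tm2 <- c(1, 2, 3, 4, 10, 11, 12, 13)
  expect_warning(fs <- cox_fit(tm2, ev, matrix(sep, ncol = 1)), "monotone")
  expect_false(fs$converged)
  expect_equal(abs(fs$beta), 20)
})

test_that("univariate screen keeps covariates below the p threshold", {
  set.seed(34)
  n <- 150
  x1 <- rnorm(n); x2 <- rnorm(n)
  tm <- rexp(n, exp(0.8 * x1)); ev <- rep(1, n)
  sc <- cox_screen(tm, ev, cbind(signal = x1, noise = x2))
  expect_true(sc$keep[sc$covariate == "signal"])
  expect_equal(sc$keep, sc$p < 0.05 & sc$converged)
})

test_that("maxstat cutpoint equals the exhaustive candidate search", {
  score <- 1:10
  tm <- score; ev <- rep(1, 10)
  res <- maxstat_cutpoint(score, tm, ev)
  expect_equal(res$candidates_evaluated, 8L)
  # independent oracle: survdiff chi2 at every in-window cut
  cand <- 2:9
  chi2 <- vapply(cand, function(cc) {
    survival::survdiff(survival::Surv(tm, ev) ~ (score > cc))$chisq
  }, numeric(1))
  expect_equal(res$cutpoint, cand[which.max(chi2)])
  expect_equal(res$max_statistic^2, max(chi2), tolerance = 1e-8)
})

test_that("maxstat is translation-equivariant and rejects degenerate input", {
  set.seed(35)
  score <- rnorm(40); tm <- rexp(40, exp(score)); ev <- rep(1, 40)
  r1 <- maxstat_cutpoint(score, tm, ev)
  r2 <- maxstat_cutpoint(score + 7, tm, ev)
  expect_equal(r2$cutpoint, r1$cutpoint + 7, tolerance = 1e-12)
  expect_equal(r2$max_statistic, r1$max_statistic, tolerance = 1e-12)
  expect_error(maxstat_cutpoint(rep(1, 40), tm, ev), "candidate")
  expect_error(maxstat_cutpoint(score[1:5], tm[1:5], ev[1:5]), ">= 10")
})

test_that("null-score maxstat statistics sit inside the permutation reference", {
  set.seed(36)
  n <- 60
  score <- rnorm(n); tm <- rexp(n); ev <- rbinom(n, 1, 0.7)
  obs <- maxstat_cutpoint(score, tm, ev)$max_statistic
  perm <- vapply(1:200, function(i)
    maxstat_cutpoint(sample(score), tm, ev)$max_statistic, numeric(1))
  expect_gte(obs, quantile(perm, 0.01))
  expect_lte(obs, quantile(perm, 0.99))
})

test_that("two-group log-rank chi2 equals the squared maxstat statistic", {
  set.seed(37)
  score <- rnorm(30); tm <- rexp(30); ev <- rep(1, 30)
  cut <- median(score)
  z2 <- logrank_test(tm, ev, ifelse(score > cut, "hi", "lo"))$chi2
  oe <- tlscore:::.logrank_z(tm, ev, score > cut)
  expect_equal(oe^2, z2, tolerance = 1e-10)
})

test_that("cox recovers the generating hazard coefficient", {
  set.seed(38)
  hits <- 0L
  for (i in 1:30) {
    n <- 300
    x <- rnorm(n)
    tm <- rexp(n, 0.05 * exp(0.7 * x))
    cens <- runif(n, 0, quantile(tm, 0.9) * 2)
    fit <- cox_fit(pmin(tm, cens), as.integer(tm <= cens),
                   matrix(x, ncol = 1))
    if (abs(fit$beta - 0.7) < 2 * fit$se) hits <- hits + 1L
  }
  expect_gte(hits, 27L)  # ~95% coverage over 30 replicates
})
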