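toy_cells <- function() {
  counts <- rbind(
    ok = c(3000, 1500, 400, 60, 40),          # passes every bound
    umi_hi = c(59800, 100, 60, 30, 10),       # total 60000 > 50000
    mito_hi = c(1000, 200, 100, 300, 0),      # 300/1600 mito
    hgb_hi = c(1400, 200, 200, 0, 200)        # 200/2000 hemoglobin
  )
  colnames(counts) <- c("G1", "G2", "G3", "MT-1", "HBB")
  storage.mode(counts) <- "integer"
  cell_matrix(counts)
}

test_that("qc metrics are derived from counts and gene annotations", {
  cm <- toy_cells()
  expect_equal(unname(cm$qc$total_umi[1]), 5000)
  expect_equal(unname(cm$qc$n_genes_detected[1]), 5L)
  expect_equal(unname(cm$qc$frac_mito[3]), 300 / 1600)
  expect_equal(unname(cm$qc$frac_hgb[4]), 200 / 2000)
})

test_that("qc filter removes strict violations and keeps boundary cells", {
  cm <- toy_cells()
  kept <- qc_filter(cm, genes_min = 3)
  expect_equal(rownames(kept$counts), "ok")
  expect_equal(unname(attr(kept, "removed")[c("umi_high", "mito", "hgb")]),
               c(1L, 1L, 1L))

  # a cell at exactly 1000 UMIs or exactly 15% mito is retained
  boundary <- rbind(at_min = c(850L, 0L, 0L, 150L, 0L),
                    rich = c(4000L, 500L, 300L, 200L, 0L))
  colnames(boundary) <- c("G1", "G2", "G3", "MT-1", "HBB")
  cmb <- cell_matrix(boundary)
  expect_equal(cmb$qc["at_min", "total_umi"], 1000)
  expect_equal(cmb$qc["at_min", "frac_mito"], 0.15)
  keptb <- qc_filter(cmb, genes_min = 2)
  expect_true("at_min" %in% rownames(keptb$counts))

  # a 60,000-UMI cell is removed
  expect_false("umi_hi" %in% rownames(qc_filter(cm, genes_min = 1)$counts))

  # idempotence
  again <- qc_filter(kept, genes_min = 3)
  expect_identical(again$counts, kept$counts)

  # removal counts bound the total removed (overlaps allowed)
  cm2 <- generate_single_cell(300, 400, c(a = 1), paste0("M", 1:8), "a",
                              seed = 61, qc_violation_frac = 0.2)
  f <- qc_filter(cm2)
  expect_lte(attr(f, "n_removed"), sum(attr(f, "removed")))
})

test_that("normalization is depth-invariant and keeps zeros", {
  counts <- rbind(a = c(10L, 9990L, 0L), b = c(20L, 19980L, 0L))
  colnames(counts) <- c("g1", "g2", "g3")
  nm <- normalize_log1p(cell_matrix(counts))
  expect_equal(nm["a", "g1"], log(11))      # total 10000: scale cancels
  expect_equal(nm["a", "g3"], 0)
  expect_equal(nm["a", ], nm["b", ])        # doubled depth, same profile

  zero <- rbind(z = c(0L, 0L, 0L), x = c(1L, 1L, 1L))
  colnames(zero) <- c("g1", "g2", "g3")
  expect_error(normalize_log1p(cell_matrix(zero)), "zero total")
})

test_that("hvg selection ranks by standardized variance with stable ties", {
  set.seed(62)
  n_cells <- 80
  base <- matrix(rpois(n_cells * 100, lambda = 5), n_cells, 100)
  colnames(base) <- sprintf("g%03d", 1:100)
  rownames(base) <- sprintf("c%02d", 1:n_cells)
  # gene g001 gets 10x variance at (roughly) equal mean
  base[, "g001"] <- pmax(0L, as.integer(round(5 + rnorm(n_cells, 0, sqrt(50)))))
  nm <- normalize_log1p(cell_matrix(base))
  hv <- select_hvgs(nm, n = 10)
  expect_equal(hv[1], "g001")
  expect_length(select_hvgs(nm, n = 37), 37L)
  expect_error(select_hvgs(nm, n = 200), "exceeds")

  # exact ties fall back to gene-id order
  tied <- matrix(rep(c(0L, 1L), each = 3), 6, 4)
  dimnames(tied) <- list(sprintf("c%d", 1:6), c("d", "b", "a", "c"))
  nmt <- normalize_log1p(cell_matrix(cbind(tied, anchor = rep(1L, 6))))
  expect_equal(select_hvgs(nmt, n = 2), c("a", "b"))
})

test_that("module scores are null-centered, linear and order-invariant", {
  set.seed(63)
  counts <- matrix(rpois(200 * 300, 4), 200, 300,
                   dimnames = list(sprintf("c%03d", 1:200),
                                   sprintf("g%03d", 1:300)))
  nm <- normalize_log1p(cell_matrix(counts))
  mod <- sample(colnames(nm), 15)
  ms <- module_score(nm, mod, seed = 2)
  # module genes drawn from the same population as their bins
  expect_lt(abs(mean(ms$score)), 0.05)

  # adding a constant to module genes raises every score by about that
  # constant (the shift also moves module genes into higher-expression bins,
  # so the matched controls rise a little too)
  nm_up <- nm; nm_up[, mod] <- nm_up[, mod] + 0.7
  ms_up <- module_score(nm_up, mod, seed = 2)
  d <- ms_up$score - ms$score
  expect_true(all(d > 0))
  expect_lt(abs(mean(d) - 0.7), 0.25)

  # gene and cell order invariance
  perm <- nm[sample(nrow(nm)), sample(ncol(nm))]
  ms_perm <- module_score(perm, mod, seed = 2)
  expect_equal(ms_perm$score[names(ms$score)], ms$score, tolerance = 1e-10)

  # a different seed moves scores by less than the score spread
  ms_seed <- module_score(nm, mod, seed = 99)
  expect_lt(mean(abs(ms_seed$score - ms$score)), sd(ms$score))

  expect_error(suppressWarnings(module_score(nm, c("nope"))), "no module gene")
  expect_warning(module_score(nm, c(mod, "ghost"), seed = 2), "absent")
})

test_that("the enriched cell type gets the top module score", {
  props <- c(tnk = 0.25, b = 0.25, myeloid = 0.2, tumor = 0.3)
  mod <- paste0("TLS", 1:23)
  cm <- generate_single_cell(500, 600, props, mod, "tnk", seed = 64,
                             enrichment = 4, qc_violation_frac = 0.05)
  cm <- qc_filter(cm)
  ms <- module_score(normalize_log1p(cm), mod, seed = 3)
  means <- tapply(ms$score, cm$cell_type, mean)
  expect_equal(names(which.max(means)), "tnk")
  p <- wilcox.test(ms$score[cm$cell_type == "tnk"],
                   ms$score[cm$cell_type != "tnk"])$p.value
  expect_lt(p, 0.01)
})

test_that("group comparison reuses the package BH adjustment", {
  set.seed(65)
  counts <- matrix(rpois(150 * 200, 4), 150, 200,
                   dimnames = list(sprintf("c%03d", 1:150),
                                   sprintf("g%03d", 1:200)))
  nm <- normalize_log1p(cell_matrix(counts))
  ms <- module_score(nm, colnames(nm)[1:10], seed = 4)
  groups <- rep(c("x", "y", "z"), each = 50)
  cmp <- compare_scores_by_group(ms, groups)
  expect_equal(nrow(cmp), 3L)
  expect_equal(cmp$adj_p, bh_adjust(cmp$p))
  expect_true(all(cmp$p > 0.01))  # identical populations

  expect_warning(
    cmp2 <- compare_scores_by_group(ms, c(rep("x", 149), "solo")),
    "singleton")
  expect_equal(nrow(cmp2), 0L)
})
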