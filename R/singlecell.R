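.default_hgb <- c("HBA1", "HBA2", "HBB", "HBD", "HBG1", "HBG2", "HBM", "HBQ1", "HBZ")

#' Cells x genes count matrix with per-cell QC metrics
#'
#' QC metrics (total UMI, detected genes, mitochondrial and hemoglobin count
#' fractions) are computed from the counts at construction time.
#' Mitochondrial genes default to the `MT-` prefix and hemoglobin genes to
#' the HBA/HBB family symbols; both are overridable for data (synthetic or
#' otherwise) that labels its own.
#'
#' @param counts non-negative integer matrix, cells in rows, genes in
#'   columns, with cell/gene dimnames.
#' @param mito_genes,hgb_genes gene ids counted as mitochondrial /
#'   hemoglobin (`NULL` = defaults above).
#' @param cell_type optional per-cell type labels.
#' @param sample optional per-cell sample labels.
#' @return An object of class `cell_matrix`: `counts`, `qc` (data.frame with
#'   `total_umi`, `n_genes_detected`, `frac_mito`, `frac_hgb`), `cell_type`,
#'   `sample`, and the gene lists used.
#' @export
cell_matrix <- function(counts, mito_genes = NULL, hgb_genes = NULL,
                        cell_type = NULL, sample = NULL) {
  if (!is.matrix(counts)) stop("'counts' must be a matrix (cells x genes)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' must have cell rownames and gene colnames")
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  genes <- colnames(counts)
  if (is.null(mito_genes)) mito_genes <- genes[startsWith(genes, "MT-")]
  if (is.null(hgb_genes)) hgb_genes <- intersect(.default_hgb, genes)
  mito_genes <- intersect(mito_genes, genes)
  hgb_genes <- intersect(hgb_genes, genes)
  total <- rowSums(counts)
  qc <- data.frame(
    total_umi = total,
    n_genes_detected = rowSums(counts > 0),
    frac_mito = if (length(mito_genes))
      rowSums(counts[, mito_genes, drop = FALSE]) / pmax(total, 1) else 0,
    frac_hgb = if (length(hgb_genes))
      rowSums(counts[, hgb_genes, drop = FALSE]) / pmax(total, 1) else 0,
    row.names = rownames(counts))
  if (!is.null(cell_type)) cell_type <- stats::setNames(as.character(cell_type), rownames(counts))
  if (!is.null(sample)) sample <- stats::setNames(as.character(sample), rownames(counts))
  structure(list(counts = counts, qc = qc, cell_type = cell_type,
                 sample = sample, mito_genes = mito_genes,
                 hgb_genes = hgb_genes),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("cell_matrix: %d cells x %d genes (median UMI %d)\n",
              nrow(x$counts), ncol(x$counts),
              as.integer(stats::median(x$qc$total_umi))))
  invisible(x)
}

#' Quality-control filter at fixed thresholds
#'
#' Removes cells with UMI counts above `umi_max` or fewer than `umi_min`,
#' detected genes above `genes_max` or fewer than `genes_min`, hemoglobin
#' count fraction above `hgb_max`, or mitochondrial fraction above
#' `mito_max`. All removals are strict inequalities, so boundary values are
#' retained (a cell with exactly `umi_min` UMIs stays). Re-filtering a
#' filtered matrix is the identity.
#'
#' @param cm a [cell_matrix()].
#' @param umi_max,umi_min,genes_max,genes_min,hgb_max,mito_max thresholds
#'   (defaults 50000, 1000, 5000, 300, 0.05, 0.15).
#' @return The filtered `cell_matrix`; per-criterion removal counts attached
#'   as attribute `"removed"`. Errors if no cell survives, listing the
#'   per-criterion counts.
#' @export
qc_filter <- function(cm, umi_max = 50000, umi_min = 1000,
                      genes_max = 5000, genes_min = 300,
                      hgb_max = 0.05, mito_max = 0.15) {
  stopifnot(inherits(cm, "cell_matrix"))
  qc <- cm$qc
  bad <- cbind(
    umi_high = qc$total_umi > umi_max,
    umi_low = qc$total_umi < umi_min,
    genes_high = qc$n_genes_detected > genes_max,
    genes_low = qc$n_genes_detected < genes_min,
    hgb = qc$frac_hgb > hgb_max,
    mito = qc$frac_mito > mito_max)
  keep <- !apply(bad, 1L, any)
  removed <- colSums(bad)
  if (!any(keep))
    stop("QC removed every cell; per-criterion counts: ",
         paste(names(removed), removed, sep = "=", collapse = ", "))
  out <- cell_matrix(cm$counts[keep, , drop = FALSE],
                     mito_genes = cm$mito_genes, hgb_genes = cm$hgb_genes,
                     cell_type = if (is.null(cm$cell_type)) NULL else cm$cell_type[keep],
                     sample = if (is.null(cm$sample)) NULL else cm$sample[keep])
  attr(out, "removed") <- removed
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Depth-normalize and log-transform counts
#'
#' `x -> ln(1 + scale * x / total_umi_cell)`: library-size normalization to a
#' fixed scale followed by natural log1p. Zeros stay zero and the result is
#' invariant to scaling a cell's counts.
#'
#' @param cm a [cell_matrix()].
#' @param scale target depth (default 10000).
#' @return A cells x genes numeric matrix.
#' @export
normalize_log1p <- function(cm, scale = 10000) {
  stopifnot(inherits(cm, "cell_matrix"))
  total <- rowSums(cm$counts)
  if (any(total == 0))
    stop("cell(s) with zero total counts (should have been QC-filtered): ",
         paste(utils::head(rownames(cm$counts)[total == 0], 5), collapse = ", "))
  log1p(scale * cm$counts / total)
}

#' Select highly variable genes by standardized variance
#'
#' Per gene, the expected variance at its mean is taken from a running-median
#' trend of log variance against log mean; gene values are standardized by
#' that expected spread (clipped at sqrt(n_cells)) and the genes with the
#' largest variance of the standardized values are returned. Ties are broken
#' deterministically by gene id.
#'
#' @param normed cells x genes matrix from [normalize_log1p()].
#' @param n number of genes to return (default 2000).
#' @return Character vector of `n` gene ids, most variable first.
#' @export
select_hvgs <- function(normed, n = 2000L) {
  G <- ncol(normed)
  if (n > G) stop("n exceeds the number of genes")
  mu <- colMeans(normed)
  v <- apply(normed, 2L, stats::var)
  expressed <- v > 0
  std_var <- numeric(G)
  names(std_var) <- colnames(normed)
  if (any(expressed)) {
    lm_ <- log10(mu[expressed])
    lv <- log10(v[expressed])
    ord <- order(lm_, colnames(normed)[expressed])
    k <- min(length(ord), max(5L, round(length(ord) / 20)))
    if (k %% 2L == 0L) k <- k + 1L
    trend <- numeric(length(ord))
    trend[ord] <- stats::runmed(lv[ord], k = k, endrule = "median")
    sd_exp <- sqrt(10^trend)
    clip <- sqrt(nrow(normed))
    Z <- sweep(sweep(normed[, expressed, drop = FALSE], 2L, mu[expressed]),
               2L, sd_exp, "/")
    Z <- pmin(pmax(Z, -clip), clip)
    std_var[expressed] <- apply(Z, 2L, stats::var)
  }
  ord_all <- order(-std_var, names(std_var))
  names(std_var)[ord_all][seq_len(n)]
}

#' Binned-control module score
#'
#' Genes are cut into `n_bins` equal-count bins of average expression across
#' cells; for each module gene, `n_ctrl` control genes are drawn from its bin
#' (excluding module genes; with replacement when the bin is small). Each
#' cell's score is its mean expression over module genes minus its mean over
#' the pooled control draws.
#'
#' @param normed cells x genes matrix from [normalize_log1p()].
#' @param module a [gene_set()] (or character vector) of module genes; genes
#'   absent from the matrix are dropped with a warning.
#' @param n_bins,n_ctrl binning and control-pool sizes (defaults 24 and 100).
#' @param seed RNG seed for the control draws.
#' @return An object of class `module_score_result`: per-cell `score`
#'   (named), `module`, `n_bins`, `n_ctrl`, `seed`.
#' @export
module_score <- function(normed, module, n_bins = 24L, n_ctrl = 100L, seed = 1L) {
  genes <- colnames(normed)
  mod <- if (inherits(module, "gene_set")) module$genes else as.character(module)
  mod_name <- if (inherits(module, "gene_set")) module$name else "module"
  missing <- setdiff(mod, genes)
  if (length(missing))
    warning(length(missing), " module gene(s) absent from matrix dropped")
  mod <- intersect(mod, genes)
  if (!length(mod)) stop("no module gene present in the matrix")
  if (length(genes) < n_bins) stop("fewer genes than bins")
  .pin_rng(seed)

  avg <- colMeans(normed)
  # id-stable ranks and sorted pools so the draws are gene-order invariant
  ord <- order(avg, genes)
  rk <- integer(length(genes)); rk[ord] <- seq_along(genes)
  bin <- ceiling(rk / (length(genes) / n_bins))
  names(bin) <- genes
  mod <- sort(mod)
  ctrl <- unlist(lapply(mod, function(g) {
    pool <- sort(genes[bin == bin[g] & !(genes %in% mod)])
    if (!length(pool)) return(character(0))
    pool[sample.int(length(pool), n_ctrl, replace = length(pool) < n_ctrl)]
  }))
  if (!length(ctrl)) stop("no control genes available in the module bins")
  score <- rowMeans(normed[, mod, drop = FALSE]) -
    rowMeans(normed[, ctrl, drop = FALSE])
  structure(list(score = score, module = mod_name, module_genes = mod,
                 n_bins = n_bins, n_ctrl = n_ctrl, seed = seed),
            class = "module_score_result")
}

#' @export
print.module_score_result <- function(x, ...) {
  cat(sprintf("module_score '%s': %d cells, mean %.3f (bins %d, ctrl %d)\n",
              x$module, length(x$score), mean(x$score), x$n_bins, x$n_ctrl))
  invisible(x)
}

#' Compare module scores across cell groups
#'
#' Pairwise Wilcoxon rank-sum tests with BH correction over all group pairs;
#' singleton groups are skipped with a warning.
#'
#' @param result a [module_score()] result.
#' @param groups per-cell labels aligned with the scored cells.
#' @return A `data.frame` with `group1`, `group2`, `p`, `adj_p`; per-group
#'   means/medians attached as attribute `"summary"`.
#' @export
compare_scores_by_group <- function(result, groups) {
  stopifnot(inherits(result, "module_score_result"))
  if (length(groups) != length(result$score)) stop("one group label per cell required")
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2L) stop("need >= 2 groups")
  singleton <- names(tab)[tab < 2L]
  if (length(singleton))
    warning("singleton group(s) skipped: ", paste(singleton, collapse = ", "))
  use <- setdiff(names(tab), singleton)
  if (length(use) < 2L) {
    return(structure(data.frame(group1 = character(), group2 = character(),
                                p = numeric(), adj_p = numeric()),
                     summary = NULL))
  }
  pairs <- utils::combn(sort(use), 2L)
  p <- apply(pairs, 2L, function(pr) {
    suppressWarnings(stats::wilcox.test(result$score[groups == pr[1L]],
                                        result$score[groups == pr[2L]])$p.value)
  })
  out <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ], p = p,
                    adj_p = bh_adjust(p), row.names = NULL)
  summ <- do.call(rbind, lapply(sort(use), function(g) data.frame(
    group = g, n = sum(groups == g),
    mean = mean(result$score[groups == g]),
    median = stats::median(result$score[groups == g]))))
  attr(out, "summary") <- summ
  out
}
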