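#' Fit the PCA signature score model
#'
#' Prognostic genes are z-scored across training samples (population, i.e.
#' 1/n, denominator) and the standardized genes x samples matrix is
#' decomposed by SVD. Components 1 and 2 (decreasing singular value) give
#' unit-norm gene loading vectors; the per-sample score is the component-1
#' score minus the component-2 score. SVD signs are arbitrary, so both
#' components are anchored so their mean loading over the favorable
#' (hazard ratio < 1) genes is non-negative; a high score then tracks the
#' favorable-gene block.
#'
#' @param m an [expression_matrix()] with unit `"logTPM"` (training cohort).
#' @param prognostic_genes gene ids entering the PCA (>= 3 present in `m`).
#' @param favorable_genes subset of `prognostic_genes` with HR < 1 used as the
#'   sign anchor; defaults to all prognostic genes.
#' @return An object of class `score_model`: `gene_ids`, `gene_means`,
#'   `gene_sds`, `loadings1`, `loadings2`, `sdev` (singular values /
#'   sqrt(n)), `sign_anchor`.
#' @export
fit_score_model <- function(m, prognostic_genes, favorable_genes = NULL) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$unit != "logTPM") stop("fit_score_model() expects unit logTPM")
  prognostic_genes <- intersect(prognostic_genes, rownames(m$values))
  if (length(prognostic_genes) < 3L) stop("need >= 3 prognostic genes present")
  if (ncol(m$values) < 3L) stop("need >= 3 samples")
  if (is.null(favorable_genes)) favorable_genes <- prognostic_genes
  favorable_genes <- intersect(favorable_genes, prognostic_genes)
  if (!length(favorable_genes)) favorable_genes <- prognostic_genes

  X <- m$values[prognostic_genes, , drop = FALSE]
  n <- ncol(X)
  mu <- rowMeans(X)
  sds <- sqrt(rowSums((X - mu)^2) / n)  # population denominator
  if (any(sds <= 0))
    stop("zero-variance prognostic gene(s): ",
         paste(utils::head(prognostic_genes[sds <= 0], 5), collapse = ", "))
  Z <- (X - mu) / sds
  sv <- svd(Z, nu = 2L, nv = 0L)
  if (length(sv$d) < 2L || sv$d[2L] <= sv$d[1L] * 1e-12)
    stop("fewer than 2 non-degenerate components")
  l1 <- sv$u[, 1L]; l2 <- sv$u[, 2L]
  names(l1) <- names(l2) <- prognostic_genes
  fav <- prognostic_genes %in% favorable_genes
  if (mean(l1[fav]) < 0) l1 <- -l1
  if (mean(l2[fav]) < 0) l2 <- -l2
  structure(list(gene_ids = prognostic_genes, gene_means = mu, gene_sds = sds,
                 loadings1 = l1, loadings2 = l2, sdev = sv$d / sqrt(n),
                 sign_anchor = favorable_genes),
            class = "score_model")
}

#' @export
print.score_model <- function(x, ...) {
  cat(sprintf("score_model: %d genes, component sd %.3f / %.3f\n",
              length(x$gene_ids), x$sdev[1L], x$sdev[2L]))
  invisible(x)
}

#' Score samples with a fitted signature model
#'
#' New cohorts are standardized with the model's stored means and standard
#' deviations (no re-fitting); the score is the projection on component 1
#' minus the projection on component 2.
#'
#' @param model a [fit_score_model()] result.
#' @param m an [expression_matrix()] with unit `"logTPM"` containing the model
#'   genes.
#' @param impute_missing if `TRUE`, genes absent from `m` are scored at the
#'   training mean (z = 0) with a warning instead of erroring.
#' @return A `data.frame` (class `score_table`) with `sample_id`, `pc1`,
#'   `pc2`, `tlsscore`.
#' @export
score_samples <- function(model, m, impute_missing = FALSE) {
  stopifnot(inherits(model, "score_model"), inherits(m, "expression_matrix"))
  if (m$unit != "logTPM") stop("score_samples() expects unit logTPM")
  present <- model$gene_ids %in% rownames(m$values)
  if (!all(present)) {
    if (!impute_missing)
      stop("model gene(s) missing from matrix: ",
           paste(utils::head(model$gene_ids[!present], 5), collapse = ", "))
    warning(sum(!present), " model gene(s) missing; imputed at training mean")
  }
  Z <- matrix(0, length(model$gene_ids), ncol(m$values),
              dimnames = list(model$gene_ids, colnames(m$values)))
  g <- model$gene_ids[present]
  Z[g, ] <- (m$values[g, , drop = FALSE] - model$gene_means[g]) / model$gene_sds[g]
  pc1 <- as.numeric(crossprod(Z, model$loadings1))
  pc2 <- as.numeric(crossprod(Z, model$loadings2))
  out <- data.frame(sample_id = colnames(m$values), pc1 = pc1, pc2 = pc2,
                    tlsscore = pc1 - pc2, row.names = NULL)
  class(out) <- c("score_table", "data.frame")
  out
}

#' Dichotomize scores at the maximally selected cutpoint
#'
#' Finds the [maxstat_cutpoint()] of the score against survival, assigns
#' high/low groups (high: score strictly above the cutpoint) and reports the
#' two-group log-rank test.
#'
#' @param scores a [score_samples()] table.
#' @param clinical clinical `data.frame` with `sample_id`, `time`, `event`.
#' @param quantile_window passed to [maxstat_cutpoint()].
#' @return The score table restricted to overlapping samples, with added
#'   `group` (`"high"`/`"low"`) and `cutpoint` columns; the
#'   `cutpoint_result` and log-rank test are attached as attributes
#'   `"cutpoint"` and `"logrank"`.
#' @export
dichotomize <- function(scores, clinical, quantile_window = c(0.1, 0.9)) {
  clinical <- validate_clinical(clinical)
  common <- intersect(scores$sample_id, clinical$sample_id)
  if (length(common) < 10L) stop("too few overlapping samples")
  sc <- scores[match(common, scores$sample_id), , drop = FALSE]
  cl <- clinical[match(common, clinical$sample_id), , drop = FALSE]
  if (sum(cl$event) < 1L) stop("no events among overlapping samples")
  cp <- maxstat_cutpoint(sc$tlsscore, cl$time, cl$event,
                         quantile_window = quantile_window)
  sc$group <- ifelse(sc$tlsscore > cp$cutpoint, "high", "low")
  sc$cutpoint <- cp$cutpoint
  lr <- logrank_test(cl$time, cl$event, sc$group)
  class(sc) <- c("score_table", "data.frame")
  attr(sc, "cutpoint") <- cp
  attr(sc, "logrank") <- lr
  sc
}

#' Cross score groups with mutation burden
#'
#' Splits TMB at its median (default) or its own maximally selected cutpoint,
#' crosses the split with the high/low score group into four strata, reports
#' the overall log-rank across strata and the Pearson/Spearman correlation
#' between score and TMB.
#'
#' @param scores a [dichotomize()]d score table (must carry `group`).
#' @param tmb named per-sample numeric TMB (names = sample ids).
#' @param clinical clinical `data.frame`.
#' @param tmb_split `"median"` (default) or `"maxstat"`.
#' @return A `data.frame` with `sample_id`, `tlsscore`, `group`, `tmb`,
#'   `tmb_group`, `stratum`; attributes `"logrank"` (across strata),
#'   `"pearson"`, `"spearman"` (each a list with `r` and `p`) and
#'   `"tmb_cutpoint"`.
#' @export
score_tmb_strata <- function(scores, tmb, clinical,
                             tmb_split = c("median", "maxstat")) {
  tmb_split <- match.arg(tmb_split)
  if (is.null(names(tmb))) stop("'tmb' must be named by sample id")
  if (!"group" %in% names(scores)) stop("scores must be dichotomized first")
  clinical <- validate_clinical(clinical)
  common <- Reduce(intersect, list(scores$sample_id, names(tmb),
                                   clinical$sample_id))
  if (length(common) < 10L) stop("too few overlapping samples")
  sc <- scores[match(common, scores$sample_id), , drop = FALSE]
  cl <- clinical[match(common, clinical$sample_id), , drop = FALSE]
  tm <- tmb[common]
  if (stats::var(tm) == 0) stop("all TMB values equal: no cutpoint")

  tmb_cut <- if (tmb_split == "median") stats::median(tm) else
    maxstat_cutpoint(tm, cl$time, cl$event)$cutpoint
  out <- data.frame(sample_id = common, tlsscore = sc$tlsscore,
                    group = sc$group, tmb = unname(tm),
                    tmb_group = ifelse(tm > tmb_cut, "high", "low"),
                    row.names = NULL)
  out$stratum <- paste0("score_", out$group, ".tmb_", out$tmb_group)
  tab <- table(out$stratum)
  if (any(tab == 0L)) {
    warning("empty stratum dropped: ", paste(names(tab)[tab == 0L], collapse = ", "))
  }
  lr <- logrank_test(cl$time, cl$event, out$stratum)
  pear <- stats::cor.test(out$tlsscore, out$tmb, method = "pearson")
  spear <- suppressWarnings(
    stats::cor.test(out$tlsscore, out$tmb, method = "spearman"))
  attr(out, "logrank") <- lr
  attr(out, "pearson") <- list(r = unname(pear$estimate), p = pear$p.value)
  attr(out, "spearman") <- list(r = unname(spear$estimate), p = spear$p.value)
  attr(out, "tmb_cutpoint") <- tmb_cut
  out
}
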