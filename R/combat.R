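#' Empirical-Bayes batch correction (parametric location/scale model)
#'
#' Removes additive and multiplicative batch effects from log-scale expression
#' with the classic parametric empirical-Bayes recipe: genes are standardized
#' by their batch-size-weighted grand mean and pooled variance; per-batch,
#' per-gene location (gamma) and scale (delta^2) effects are estimated and
#' shrunk toward a normal / inverse-gamma prior whose hyperparameters are fit
#' by the method of moments across genes; the corrected values are
#' back-transformed so each gene keeps its grand mean.
#'
#' @param m an [expression_matrix()] with unit `"logTPM"`.
#' @param batch per-sample batch labels; defaults to `m$batch`.
#' @param mean_only if `TRUE`, skip the empirical-Bayes model and align
#'   per-batch gene means directly (exact location removal, scales untouched).
#' @return An [expression_matrix()] (unit `"logTPM"`) with the batch structure
#'   removed; genes with zero pooled variance are passed through unchanged with
#'   a warning.
#' @export
combat_correct <- function(m, batch = NULL, mean_only = FALSE) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$unit != "logTPM") stop("combat_correct() expects unit logTPM, got ", m$unit)
  if (is.null(batch)) batch <- m$batch
  if (is.null(batch)) stop("no batch labels supplied")
  if (length(batch) != ncol(m$values)) stop("'batch' must have one label per sample")
  batch <- factor(as.character(batch))
  if (nlevels(batch) == 1L) return(m)  # identity contract
  sizes <- table(batch)
  if (any(sizes < 2L))
    stop("batch(es) with a single sample: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))

  X <- m$values
  G <- nrow(X); N <- ncol(X)
  idx <- split(seq_len(N), batch)
  nb <- lengths(idx)

  batch_means <- vapply(idx, function(j) rowMeans(X[, j, drop = FALSE]),
                        numeric(G))  # G x B
  grand_mean <- as.numeric(batch_means %*% (nb / N))
  resid <- X - batch_means[, batch[seq_len(N)], drop = FALSE]
  var_pooled <- rowSums(resid^2) / N

  degenerate <- var_pooled <= .Machine$double.eps
  if (any(degenerate))
    warning(sprintf("%d gene(s) with zero pooled variance passed through unchanged",
                    sum(degenerate)))
  keep <- which(!degenerate)
  out <- X
  if (length(keep)) {
    Z <- (X[keep, , drop = FALSE] - grand_mean[keep]) / sqrt(var_pooled[keep])
    for (b in levels(batch)) {
      j <- idx[[b]]
      Zb <- Z[, j, drop = FALSE]
      n_b <- length(j)
      gamma_hat <- rowMeans(Zb)
      if (mean_only) {
        # direct per-batch gene-mean alignment, no shrinkage
        Z[, j] <- Zb - gamma_hat
      } else {
        delta_hat <- apply(Zb, 1L, stats::var)
        fit <- .eb_location_scale(Zb, gamma_hat, delta_hat, n_b)
        Z[, j] <- (Zb - fit$gamma) / sqrt(fit$delta)
      }
    }
    out[keep, ] <- Z * sqrt(var_pooled[keep]) + grand_mean[keep]
    # pin the per-gene grand mean to the input's exactly
    out[keep, ] <- out[keep, ] - rowMeans(out[keep, , drop = FALSE]) +
      rowMeans(X[keep, , drop = FALSE])
  }
  expression_matrix(out, "logTPM", batch = NULL)
}

# Joint EB shrinkage of per-gene batch location and scale: normal prior on
# gamma (moments across genes), inverse-gamma prior on delta^2 (moments), then
# the standard fixed-point iteration between the two posterior modes.
.eb_location_scale <- function(Zb, gamma_hat, delta_hat, n_b,
                               tol = 1e-4, max_iter = 200L) {
  gamma_bar <- mean(gamma_hat)
  t2 <- stats::var(gamma_hat)
  m1 <- mean(delta_hat)
  s2 <- stats::var(delta_hat)
  if (!is.finite(t2) || t2 <= 0 || !is.finite(s2) || s2 <= 0)
    return(list(gamma = gamma_hat, delta = pmax(delta_hat, .Machine$double.eps)))
  a_prior <- (2 * s2 + m1^2) / s2
  b_prior <- (m1 * s2 + m1^3) / s2
  gamma_star <- gamma_hat
  delta_star <- delta_hat
  sum_sq <- function(g) rowSums((Zb - g)^2)
  for (i in seq_len(max_iter)) {
    g_new <- (n_b * t2 * gamma_hat + delta_star * gamma_bar) /
             (n_b * t2 + delta_star)
    d_new <- (b_prior + 0.5 * sum_sq(g_new)) / (n_b / 2 + a_prior - 1)
    change <- max(abs(g_new - gamma_star) / pmax(abs(gamma_star), 1e-8),
                  abs(d_new - delta_star) / pmax(abs(delta_star), 1e-8))
    gamma_star <- g_new
    delta_star <- d_new
    if (change < tol) break
  }
  list(gamma = gamma_star, delta = pmax(delta_star, .Machine$double.eps))
}
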