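#' Moderated two-group t-test with empirical-Bayes variance shrinkage
#'
#' Per gene, the pooled two-sample variance `s_g^2` (d residual df) is shrunk
#' toward a prior `s0^2` with `d0` prior df, both fitted by moment matching on
#' `log s_g^2` (digamma/trigamma matching of a scaled chi-square model). The
#' moderated statistic is the mean difference over `s_tilde *
#' sqrt(1/n1 + 1/n2)` with `d0 + d` degrees of freedom, BH-adjusted.
#'
#' The log fold change is the second group minus the first, groups ordered
#' lexicographically.
#'
#' @param m an [expression_matrix()] with unit `"logTPM"`.
#' @param groups two-level per-sample labels.
#' @param adj_threshold BH-adjusted p-value cutoff marking `selected` genes
#'   (default 0.01).
#' @param prior_df override of the prior df `d0`: `NULL` (estimate, default),
#'   `0` (reduces to the ordinary pooled-variance t) or `Inf` (fully shrunk).
#' @return A `data.frame` (class `deg_table`) with columns `gene_id`,
#'   `log_fc`, `t_stat`, `p`, `adj_p`, `selected`, `zero_var`; the fitted
#'   `d0` and `s0^2` and the group sizes are attached as attributes.
#' @export
moderated_t <- function(m, groups, adj_threshold = 0.01, prior_df = NULL) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$unit != "logTPM") stop("moderated_t() expects unit logTPM")
  groups <- as.character(groups)
  if (length(groups) != ncol(m$values)) stop("one group label per sample required")
  lev <- sort(unique(groups))
  if (length(lev) != 2L) stop("exactly two groups required")
  n1 <- sum(groups == lev[1L]); n2 <- sum(groups == lev[2L])
  if (n1 < 2L || n2 < 2L)
    stop("both groups need >= 2 samples (got ", n1, ", ", n2, ")")

  X1 <- m$values[, groups == lev[1L], drop = FALSE]
  X2 <- m$values[, groups == lev[2L], drop = FALSE]
  mean1 <- rowMeans(X1); mean2 <- rowMeans(X2)
  v1 <- rowSums((X1 - mean1)^2) / (n1 - 1L)
  v2 <- rowSums((X2 - mean2)^2) / (n2 - 1L)
  d <- n1 + n2 - 2L
  s2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / d
  zero_var <- s2 <= .Machine$double.eps

  if (is.null(prior_df)) {
    fit <- .fit_variance_prior(s2[!zero_var], d)
    d0 <- fit$d0; s0_2 <- fit$s0_2
  } else if (prior_df == 0) {
    d0 <- 0; s0_2 <- mean(s2[!zero_var])
  } else {
    d0 <- prior_df
    s0_2 <- exp(mean(log(s2[!zero_var])))
  }

  s_mod2 <- if (is.infinite(d0)) rep(s0_2, length(s2)) else
    (d0 * s0_2 + d * s2) / (d0 + d)
  diff <- mean2 - mean1
  se <- sqrt(s_mod2 * (1 / n1 + 1 / n2))
  t_stat <- ifelse(se > 0, diff / se, 0)
  df_total <- d0 + d
  p <- 2 * stats::pt(-abs(t_stat), df = df_total)
  adj_p <- bh_adjust(p)

  out <- data.frame(gene_id = rownames(m$values), log_fc = diff,
                    t_stat = t_stat, p = p, adj_p = adj_p,
                    selected = adj_p < adj_threshold,
                    zero_var = zero_var, row.names = NULL)
  class(out) <- c("deg_table", "data.frame")
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- s0_2
  attr(out, "group_sizes") <- stats::setNames(c(n1, n2), lev)
  attr(out, "adj_threshold") <- adj_threshold
  out
}

# Fit (d0, s0^2) so that log s^2 matches the moments of log of a scaled F:
# e_g = log s_g^2 - digamma(d/2) + log(d/2) has mean log s0^2 and excess
# variance trigamma(d0/2) beyond trigamma(d/2).
.fit_variance_prior <- function(s2, d) {
  s2 <- pmax(s2, 1e-300)
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  ebar <- mean(e)
  excess <- mean((e - ebar)^2) * length(e) / (length(e) - 1L) - trigamma(d / 2)
  if (!is.finite(excess) || excess <= 0)
    return(list(d0 = Inf, s0_2 = exp(ebar)))
  d0 <- 2 * .trigamma_inverse(excess)
  list(d0 = d0, s0_2 = exp(ebar + digamma(d0 / 2) - log(d0 / 2)))
}

# Newton solve of trigamma(x) = y (y > 0), monotone decreasing.
.trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `adj_p(i) = min over j with p(j) >= p(i) of min(1, p(j) * m / rank(j))`,
#' computed by the usual descending cumulative minimum; monotone in p and
#' invariant to input order.
#'
#' @param p vector of p-values in [0,1].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0,1]")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  ord <- order(p, decreasing = TRUE)
  adj <- pmin(1, p[ord] * m / (m:1))
  adj <- cummin(adj)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Classical group comparison tests
#'
#' Thin dispatch over the classical tests used for descriptive comparisons:
#' two-sided pooled-variance Student's t, Wilcoxon rank-sum (exact where
#' available, normal approximation with tie correction otherwise), or one-way
#' ANOVA.
#'
#' @param values numeric per-sample vector.
#' @param groups per-sample labels (2 groups for t/wilcoxon, 2+ for anova).
#' @param test one of `"t"`, `"wilcoxon"`, `"anova"`.
#' @return A list with `statistic` and `p`.
#' @export
compare_groups <- function(values, groups, test = c("t", "wilcoxon", "anova")) {
  test <- match.arg(test)
  groups <- as.character(groups)
  if (length(values) != length(groups)) stop("values/groups length mismatch")
  lev <- sort(unique(groups))
  if (length(lev) < 2L || any(table(groups) == 0L)) stop("need >= 2 non-empty groups")
  if (test %in% c("t", "wilcoxon") && length(lev) != 2L)
    stop("'", test, "' requires exactly two groups")
  x <- values[groups == lev[1L]]
  y <- values[groups == lev[2L]]
  switch(test,
    t = {
      ht <- stats::t.test(x, y, var.equal = TRUE)
      list(statistic = unname(ht$statistic), p = ht$p.value)
    },
    wilcoxon = {
      if (stats::var(values) == 0) {
        warning("constant values: Wilcoxon p set to 1")
        return(list(statistic = length(x) * length(y) / 2, p = 1))
      }
      ht <- suppressWarnings(stats::wilcox.test(x, y))
      list(statistic = unname(ht$statistic), p = ht$p.value)
    },
    anova = {
      ht <- stats::oneway.test(values ~ factor(groups), var.equal = TRUE)
      list(statistic = unname(ht$statistic), p = ht$p.value)
    })
}
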