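#' Subsampled consensus clustering with PAC-based choice of k
#'
#' For each resampling repetition a fraction of samples is drawn without
#' replacement and clustered at every k in `k_range`; the consensus matrix
#' entry for a sample pair is the fraction of co-samplings in which the pair
#' was co-assigned. The cluster number is chosen by minimizing the proportion
#' of ambiguous clustering (PAC) and final labels come from hierarchical
#' clustering of 1 - consensus at the chosen k.
#'
#' Feature rows are z-scored before clustering so every gene weighs equally
#' in the sample distances. The inner clusterer is hierarchical with
#' (1 - Pearson correlation) distance and average linkage;
#' `method = "kmeans"` is available for speed.
#'
#' @param m an [expression_matrix()].
#' @param features gene ids to cluster on (rows of `m`); default all genes.
#' @param k_range integer cluster numbers to evaluate (default 2:9).
#' @param n_reps number of subsampling repetitions (default 1000).
#' @param subsample_frac fraction of samples drawn per repetition.
#' @param seed RNG seed.
#' @param method inner clusterer, `"hclust"` (default) or `"kmeans"`.
#' @param pac_window lower/upper bounds of the ambiguity window passed to
#'   [pac()].
#' @return An object of class `consensus_result`: per-k consensus matrices and
#'   labels, per-k PAC values, `chosen_k`, final `labels`, and the resampling
#'   settings.
#' @export
consensus_cluster <- function(m, features = NULL, k_range = 2:9,
                              n_reps = 1000L, subsample_frac = 0.8, seed = 1L,
                              method = c("hclust", "kmeans"),
                              pac_window = c(0.1, 0.9)) {
  stopifnot(inherits(m, "expression_matrix"))
  method <- match.arg(method)
  if (is.null(features)) features <- rownames(m$values)
  X <- subset_expression(m, genes = features)$values  # features x samples
  n <- ncol(X)
  if (n < max(k_range) * 2L) stop("too few samples for requested k_range")
  rv <- apply(X, 1L, stats::var)
  if (all(rv <= .Machine$double.eps))
    stop("all features have zero variance")
  # z-score feature rows so every gene weighs equally in the sample distances
  X <- X[rv > .Machine$double.eps, , drop = FALSE]
  X <- (X - rowMeans(X)) / sqrt(rv[rv > .Machine$double.eps])
  .pin_rng(seed)

  n_sub <- max(round(subsample_frac * n), max(k_range) + 1L)
  co_sampled <- matrix(0, n, n)
  co_assigned <- lapply(k_range, function(k) matrix(0, n, n))
  names(co_assigned) <- as.character(k_range)

  for (rep in seq_len(n_reps)) {
    idx <- if (n_sub >= n) seq_len(n) else sort(sample.int(n, n_sub))
    co_sampled[idx, idx] <- co_sampled[idx, idx] + 1
    labels_k <- .cluster_at_ks(X[, idx, drop = FALSE], k_range, method)
    for (ki in seq_along(k_range)) {
      lab <- labels_k[[ki]]
      same <- outer(lab, lab, "==") * 1
      co_assigned[[ki]][idx, idx] <- co_assigned[[ki]][idx, idx] + same
    }
  }

  never <- co_sampled == 0
  diag(never) <- FALSE
  if (any(never))
    warning(sprintf("%d sample pair(s) never co-sampled; consensus set to 0",
                    sum(never) / 2))
  denom <- co_sampled
  denom[denom == 0] <- 1
  consensus <- lapply(co_assigned, function(A) {
    C <- A / denom
    C[never] <- 0
    diag(C) <- 1
    dimnames(C) <- list(colnames(X), colnames(X))
    C
  })

  pac_values <- vapply(consensus, pac, numeric(1),
                       lower = pac_window[1], upper = pac_window[2])
  chosen_k <- choose_k(stats::setNames(pac_values, k_range))

  labels_per_k <- lapply(seq_along(k_range), function(ki) {
    hc <- stats::hclust(stats::as.dist(1 - consensus[[ki]]), method = "average")
    stats::setNames(stats::cutree(hc, k = k_range[ki]), colnames(X))
  })
  names(labels_per_k) <- as.character(k_range)

  structure(list(k_range = k_range, consensus = consensus,
                 pac = stats::setNames(pac_values, k_range),
                 chosen_k = chosen_k,
                 labels = labels_per_k[[as.character(chosen_k)]],
                 labels_per_k = labels_per_k,
                 n_reps = n_reps, subsample_frac = subsample_frac,
                 method = method, seed = seed),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: k in {%s}, chosen k = %d (PAC %.4f), %d reps\n",
              paste(x$k_range, collapse = ","), x$chosen_k,
              x$pac[as.character(x$chosen_k)], x$n_reps))
  invisible(x)
}

# Cluster a features x samples block once per k. hclust builds one tree and
# cuts it at each k; kmeans runs per k with a deterministic multi-start.
.cluster_at_ks <- function(X, k_range, method) {
  if (method == "hclust") {
    d <- stats::as.dist(1 - stats::cor(X))
    d[!is.finite(d)] <- 1
    hc <- stats::hclust(d, method = "average")
    lapply(k_range, function(k) stats::cutree(hc, k = k))
  } else {
    lapply(k_range, function(k)
      stats::kmeans(t(X), centers = k, nstart = 3L, iter.max = 25L)$cluster)
  }
}

#' Proportion of ambiguous clustering
#'
#' The fraction of strictly-upper-triangle consensus entries falling in the
#' ambiguity window, i.e. F(upper) - F(lower) of the empirical CDF; entries
#' are counted when `lower < x <= upper`.
#'
#' @param consensus symmetric consensus matrix in [0,1].
#' @param lower,upper ambiguity window bounds (defaults 0.1 and 0.9).
#' @return PAC value in [0,1].
#' @export
pac <- function(consensus, lower = 0.1, upper = 0.9) {
  if (lower >= upper) stop("'lower' must be < 'upper'")
  x <- consensus[upper.tri(consensus)]
  if (!length(x)) stop("consensus matrix has no off-diagonal entries")
  mean(x > lower & x <= upper)
}

#' Choose the cluster number minimizing PAC
#'
#' @param pac_values named numeric vector of PAC values, names = k.
#' @return The k with minimal PAC; ties broken toward smaller k.
#' @export
choose_k <- function(pac_values) {
  k <- as.integer(names(pac_values))
  ord <- order(pac_values, k)
  k[ord[1L]]
}
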