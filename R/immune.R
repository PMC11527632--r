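#' Single-sample gene-set enrichment (ssGSEA)
#'
#' For each sample independently, genes are ranked by expression (descending,
#' ties by average rank) and the enrichment score is the sum over all gene
#' positions of the difference between the rank-weighted in-set ECDF
#' (weights `rank^alpha`, normalized to 1 over the set) and the unweighted
#' out-of-set ECDF. Scores depend on a sample's column only, and are
#' invariant to strictly increasing transforms of it.
#'
#' @param m an [expression_matrix()] (any unit; only ranks are used).
#' @param sets a list of [gene_set()] objects (or a single one).
#' @param alpha rank-weighting exponent (default 0.25, the original ssGSEA
#'   choice; 0 gives the unweighted ECDF difference).
#' @param normalize if `TRUE`, rescale all scores by the global max - min of
#'   the table.
#' @return A samples x sets numeric matrix (class kept plain); attributes
#'   `"alpha"` and `"normalized"` record the settings. Sets with no gene in
#'   the matrix give `NA` with a warning; a set covering every gene is an
#'   error.
#' @export
ssgsea <- function(m, sets, alpha = 0.25, normalize = FALSE) {
  stopifnot(inherits(m, "expression_matrix"))
  if (inherits(sets, "gene_set")) sets <- list(sets)
  set_names <- vapply(sets, `[[`, "", "name")
  genes <- rownames(m$values)
  N <- length(genes)
  members <- lapply(sets, function(s) {
    idx <- genes %in% s$genes
    if (sum(idx) == N) stop("gene set '", s$name, "' covers all genes")
    idx
  })
  empty <- vapply(members, function(i) !any(i), logical(1))
  if (any(empty))
    warning("set(s) with no gene in the matrix scored NA: ",
            paste(set_names[empty], collapse = ", "))

  scores <- matrix(NA_real_, ncol(m$values), length(sets),
                   dimnames = list(colnames(m$values), set_names))
  for (s in seq_len(ncol(m$values))) {
    x <- m$values[, s]
    r <- rank(x, ties.method = "average")      # N = highest expression
    ord <- order(r, decreasing = TRUE)
    w <- r[ord]^alpha
    for (k in seq_along(sets)) {
      if (empty[k]) next
      inset <- members[[k]][ord]
      p_in <- cumsum(w * inset) / sum(w[inset])
      p_out <- cumsum(!inset) / sum(!inset)
      scores[s, k] <- sum(p_in - p_out)
    }
  }
  if (normalize) {
    rng <- range(scores, na.rm = TRUE)
    if (diff(rng) > 0) scores <- scores / diff(rng)
  }
  attr(scores, "alpha") <- alpha
  attr(scores, "normalized") <- normalize
  scores
}

#' ESTIMATE-style stromal, immune and purity scores
#'
#' Stromal and immune scores are unnormalized ssGSEA enrichment scores of the
#' two supplied sets; their sum is the ESTIMATE score, mapped to tumor purity
#' by the published cosine calibration
#' `purity = cos(0.6049872018 + 0.0001467884 * estimate)`. The calibration
#' was fitted on a different platform's score scale, so purity values from
#' arbitrary gene sets are indicative only; values outside [0,1] are clamped
#' with a warning.
#'
#' @param m an [expression_matrix()].
#' @param stromal_set,immune_set [gene_set()] objects.
#' @return A `data.frame` with `sample_id`, `stromal`, `immune`, `estimate`,
#'   `purity`.
#' @export
estimate_scores <- function(m, stromal_set, immune_set) {
  es <- ssgsea(m, list(stromal_set, immune_set), alpha = 0.25,
               normalize = FALSE)
  est <- es[, 1L] + es[, 2L]
  purity <- cos(0.6049872018 + 0.0001467884 * est)
  if (any(purity < 0 | purity > 1)) {
    warning("purity outside [0,1] clamped (estimate score beyond the ",
            "calibration's monotone domain)")
    purity <- pmin(pmax(purity, 0), 1)
  }
  data.frame(sample_id = colnames(m$values), stromal = unname(es[, 1L]),
             immune = unname(es[, 2L]), estimate = unname(est),
             purity = unname(purity), row.names = NULL)
}
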