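# Small in-code fixtures shared across test files.

# genes x samples matrix with ids, wrapped as an expression_matrix
make_expr <- function(values, unit = "logTPM", batch = NULL,
                      genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expression_matrix(values, unit, batch = batch)
}

# two gaussian sample blobs separated on every gene, shift direction
# alternating across genes so correlation distance sees the split
make_blobs <- function(n_per = 20, n_genes = 30, sep = 6, sd = 1, seed = 42) {
  set.seed(seed)
  shift <- rep(c(0, sep), each = n_per)
  dir <- rep_len(c(1, -1), n_genes)
  X <- matrix(rnorm(n_genes * 2 * n_per, sd = sd), n_genes) + outer(dir, shift)
  list(m = make_expr(X), truth = rep(c("A", "B"), each = n_per))
}

# small synthetic cohort (single batch) used in several files
small_cohort <- function(seed = 1, ...) {
  generate_bulk_cohort(cohort_spec(n_samples = 120L, n_genes = 200L,
                                   n_batches = 1L, batch_shift = 0,
                                   batch_scale = 1, seed = seed, ...))
}
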