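#' Expression matrix container
#'
#' A genes x samples numeric matrix with a declared unit. Units move only
#' through the declared operations ([fpkm_to_tpm()], [log_transform()],
#' [combat_correct()]), so downstream stages can refuse input on the wrong
#' scale instead of silently mis-scoring it.
#'
#' @param values numeric matrix, genes in rows, samples in columns; must carry
#'   rownames (gene ids) and colnames (sample ids).
#' @param unit one of `"FPKM"`, `"TPM"`, `"logTPM"`, `"counts"`.
#' @param batch optional per-sample batch labels (length `ncol(values)`).
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `unit` and `batch`.
#' @export
expression_matrix <- function(values, unit = c("FPKM", "TPM", "logTPM", "counts"),
                              batch = NULL) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (genes x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ", paste(unique(rownames(values)[duplicated(rownames(values))])[1:3], collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (!all(is.finite(values)))
    stop("expression values must be finite")
  if (unit %in% c("FPKM", "TPM", "counts") && any(values < 0))
    stop(unit, " values must be non-negative")
  if (!is.null(batch)) {
    if (length(batch) != ncol(values))
      stop("'batch' must have one label per sample")
    batch <- as.character(batch)
    names(batch) <- colnames(values)
  }
  structure(list(values = values, unit = unit, batch = batch),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples [%s]%s\n",
              nrow(x$values), ncol(x$values), x$unit,
              if (is.null(x$batch)) "" else sprintf(", %d batches", length(unique(x$batch)))))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by gene and/or sample ids
#'
#' @param m an [expression_matrix()].
#' @param genes,samples character vectors of ids to keep (default: all).
#' @return An `expression_matrix` restricted to the requested ids.
#' @export
subset_expression <- function(m, genes = NULL, samples = NULL) {
  stopifnot(inherits(m, "expression_matrix"))
  v <- m$values
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(v))
    if (length(missing))
      stop("genes absent from matrix: ", paste(utils::head(missing, 5), collapse = ", "))
    v <- v[genes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(v))
    if (length(missing))
      stop("samples absent from matrix: ", paste(utils::head(missing, 5), collapse = ", "))
    v <- v[, samples, drop = FALSE]
  }
  b <- if (is.null(m$batch)) NULL else m$batch[colnames(v)]
  expression_matrix(v, m$unit, batch = b)
}

#' Convert FPKM to TPM
#'
#' Per sample, TPM is the FPKM value divided by the sample's FPKM total and
#' rescaled to one million, so every column sums to 1e6 exactly.
#'
#' @param m an [expression_matrix()] with unit `"FPKM"`.
#' @return An `expression_matrix` with unit `"TPM"`.
#' @export
fpkm_to_tpm <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$unit != "FPKM") stop("fpkm_to_tpm() expects unit FPKM, got ", m$unit)
  totals <- colSums(m$values)
  zero <- totals <= 0
  if (any(zero))
    stop("all-zero expression in sample(s): ",
         paste(colnames(m$values)[zero], collapse = ", "))
  out <- sweep(m$values, 2, totals, "/") * 1e6
  expression_matrix(out, "TPM", batch = m$batch)
}

#' Log2 transform TPM values
#'
#' @param m an [expression_matrix()] with unit `"TPM"`.
#' @param pseudocount added before taking log2 (default 1).
#' @return An `expression_matrix` with unit `"logTPM"`.
#' @export
log_transform <- function(m, pseudocount = 1) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$unit != "TPM") stop("log_transform() expects unit TPM, got ", m$unit)
  if (any(m$values < 0)) stop("negative TPM values")
  out <- log2(m$values + pseudocount)
  res <- expression_matrix(out, "logTPM", batch = m$batch)
  attr(res, "pseudocount") <- pseudocount
  res
}

#' Invert the log2 transform
#'
#' @param m an [expression_matrix()] with unit `"logTPM"`.
#' @param pseudocount the pseudocount used by [log_transform()].
#' @return An `expression_matrix` with unit `"TPM"`.
#' @export
inverse_log_transform <- function(m, pseudocount = 1) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$unit != "logTPM") stop("inverse_log_transform() expects unit logTPM")
  out <- pmax(2^m$values - pseudocount, 0)
  expression_matrix(out, "TPM", batch = m$batch)
}
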