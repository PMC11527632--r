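# Readers/writers for the plain-text formats the pipeline exchanges:
# genes-in-rows expression TSV/CSV, clinical tables, GMT gene sets, MAF-like
# mutation tables, and MTX triplets for single-cell counts.

.sniff_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else "\t"
}

#' Read a genes-in-rows expression table
#'
#' Delimiter (tab or comma) is sniffed from the first line; `"."`, `"NA"` and
#' empty fields are treated as missing and rejected (the container requires
#' finite values). If a clinical table is supplied and the first column of the
#' file matches its sample ids, the matrix is assumed transposed
#' (samples-in-rows) and flipped with a warning. Duplicate gene symbols are
#' collapsed by keeping the row with the highest variance.
#'
#' @param path file path.
#' @param unit declared unit of the stored values.
#' @param clinical optional clinical `data.frame` (see [read_clinical_tsv()])
#'   used only for orientation detection.
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(path, unit = "TPM", clinical = NULL) {
  sep <- .sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          na.strings = c("NA", ".", ""), quote = "\"",
                          comment.char = "#", stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  if (!is.null(clinical) && mean(ids %in% clinical$sample_id) > 0.5) {
    warning("first column matches clinical sample ids; transposing to genes-in-rows")
    vals <- t(vals)
  }
  if (anyNA(vals)) stop("missing values in expression table: ", path)
  if (anyDuplicated(rownames(vals))) {
    keep <- tapply(seq_len(nrow(vals)), rownames(vals), function(i) {
      i[which.max(apply(vals[i, , drop = FALSE], 1, stats::var))]
    })
    message(sprintf("collapsed %d duplicated gene symbols (kept max-variance row)",
                    nrow(vals) - length(keep)))
    vals <- vals[sort(unname(keep)), , drop = FALSE]
  }
  expression_matrix(vals, unit)
}

#' Write an expression matrix as genes-in-rows TSV
#'
#' @param m an [expression_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(m, path) {
  stopifnot(inherits(m, "expression_matrix"))
  df <- data.frame(gene_id = rownames(m$values), m$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' Expects columns `sample_id`, `time`, `event` plus optional covariates.
#'
#' @param path file path (TSV or CSV; delimiter sniffed).
#' @return A `data.frame` with validated survival columns.
#' @export
read_clinical_tsv <- function(path) {
  sep <- .sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          na.strings = c("NA", ".", ""), stringsAsFactors = FALSE)
  validate_clinical(df)
}

#' Validate a clinical table
#'
#' @param df data.frame with `sample_id`, `time`, `event` columns.
#' @return The validated `data.frame`.
#' @export
validate_clinical <- function(df) {
  need <- c("sample_id", "time", "event")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("clinical table lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in clinical table")
  if (any(!is.finite(df$time)) || any(df$time < 0)) stop("survival times must be finite and >= 0")
  if (!all(df$event %in% c(0, 1))) stop("event indicator must be 0/1")
  df
}

#' @rdname read_clinical_tsv
#' @param df clinical `data.frame`.
#' @param path output path.
#' @export
write_clinical_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gene set constructor
#'
#' @param name set name.
#' @param genes character vector of gene symbols (must be unique).
#' @param category optional category annotation (e.g. "chemokine").
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(name, genes, category = NULL) {
  genes <- as.character(genes)
  if (!length(genes)) stop("empty gene set: ", name)
  if (anyDuplicated(genes)) stop("duplicate genes within set: ", name)
  structure(list(name = name, category = category, genes = genes),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s' (%s): %d genes\n", x$name,
              if (is.null(x$category)) "-" else x$category, length(x$genes)))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields name, description,
#' then genes. The description is kept as the set category.
#'
#' @param path GMT file path.
#' @return Named list of [gene_set()] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) stop("malformed GMT line: ", substr(l, 1, 40))
    gene_set(parts[1L], parts[-(1:2)], category = parts[2L])
  })
  stats::setNames(sets, vapply(sets, `[[`, "", "name"))
}

#' Write gene sets to a GMT file
#'
#' @param sets list of [gene_set()] objects.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, if (is.null(s$category)) "NA" else s$category, s$genes),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' The packaged 23-gene TLS signature
#'
#' The TLS-related gene (TLSRG) signature shipped with the package: 23 genes in
#' eight functional categories (6 chemokines, 2 chemokine receptors,
#' 2 cytokines, 4 transcription factors, 4 co-stimulatory molecules,
#' 2 inhibitory receptors, 2 cytokine receptors, 1 ECM-associated molecule).
#'
#' @param as one of `"set"` (a single [gene_set()] of all 23 genes),
#'   `"table"` (a `data.frame` with `gene` and `category` columns) or
#'   `"collection"` (the per-category gene sets).
#' @return See `as`.
#' @export
tls_signature <- function(as = c("set", "table", "collection")) {
  as <- match.arg(as)
  path <- system.file("extdata", "tlsrg_signature.gmt", package = "tlscore",
                      mustWork = TRUE)
  sets <- read_gmt(path)
  switch(as,
    set = sets[["TLSRG"]],
    collection = sets[names(sets) != "TLSRG"],
    table = {
      cats <- sets[names(sets) != "TLSRG"]
      do.call(rbind, lapply(unname(cats), function(s)
        data.frame(gene = s$genes, category = s$category)))
    })
}

#' Read a MAF-like mutation table
#'
#' Requires at least `Tumor_Sample_Barcode`, `Hugo_Symbol`,
#' `Variant_Classification` columns.
#'
#' @param path TSV path.
#' @return A `data.frame`.
#' @export
read_maf_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          quote = "", comment.char = "#", stringsAsFactors = FALSE)
  need <- c("Tumor_Sample_Barcode", "Hugo_Symbol", "Variant_Classification")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("MAF table lacks column(s): ", paste(missing, collapse = ", "))
  df
}

#' Write a cells x genes count matrix as MTX triplet plus id files
#'
#' @param cm a [cell_matrix()].
#' @param dir output directory (created if needed); writes `matrix.mtx`
#'   (genes x cells, Matrix Market), `genes.tsv` and `barcodes.tsv`.
#' @export
write_cell_mtx <- function(cm, dir) {
  stopifnot(inherits(cm, "cell_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- Matrix::Matrix(t(cm$counts), sparse = TRUE)
  Matrix::writeMM(sp, file.path(dir, "matrix.mtx"))
  writeLines(colnames(cm$counts), file.path(dir, "genes.tsv"))
  writeLines(rownames(cm$counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a cells x genes count matrix from an MTX triplet directory
#'
#' @param dir directory containing `matrix.mtx` (genes x cells), `genes.tsv`,
#'   `barcodes.tsv`.
#' @param mito_genes,hgb_genes gene-id sets used to recompute QC fractions.
#' @return A [cell_matrix()].
#' @export
read_cell_mtx <- function(dir, mito_genes = NULL, hgb_genes = NULL) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- readLines(file.path(dir, "barcodes.tsv"))
  counts <- t(m)
  dimnames(counts) <- list(cells, genes)
  cell_matrix(counts, mito_genes = mito_genes, hgb_genes = hgb_genes)
}
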