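#' Pipeline configuration
#'
#' Collects every threshold of the derivation chain with the published
#' defaults: DEG adjusted p < 0.01, univariate Cox p < 0.05, consensus
#' clustering over k = 2..9 with 1000 repetitions at 80% subsampling, PAC
#' window (0.1, 0.9), maxstat candidate window at the 10-90% score quantiles,
#' ssGSEA alpha 0.25, and the single-cell QC bounds (UMI 1,000-50,000,
#' detected genes 300-5,000, hemoglobin <= 5%, mitochondrial <= 15%).
#'
#' @param adj_p BH-adjusted p cutoff for DEG selection.
#' @param cox_p univariate Cox screen cutoff.
#' @param k_range,n_reps,subsample_frac consensus clustering settings.
#' @param pac_window PAC ambiguity window.
#' @param maxstat_window quantile window for cutpoint candidates.
#' @param alpha ssGSEA rank-weight exponent.
#' @param qc named list of QC bounds (see [qc_filter()]).
#' @param cluster_method inner clusterer for [consensus_cluster()].
#' @param seed integer seed governing all stochastic stages.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(adj_p = 0.01, cox_p = 0.05, k_range = 2:9,
                            n_reps = 1000L, subsample_frac = 0.8,
                            pac_window = c(0.1, 0.9),
                            maxstat_window = c(0.1, 0.9), alpha = 0.25,
                            qc = list(umi_max = 50000, umi_min = 1000,
                                      genes_max = 5000, genes_min = 300,
                                      hgb_max = 0.05, mito_max = 0.15),
                            cluster_method = "hclust", seed = 1L) {
  cfg <- list(adj_p = adj_p, cox_p = cox_p, k_range = as.integer(k_range),
              n_reps = as.integer(n_reps), subsample_frac = subsample_frac,
              pac_window = pac_window, maxstat_window = maxstat_window,
              alpha = alpha, qc = qc, cluster_method = cluster_method,
              seed = as.integer(seed))
  if (cfg$adj_p <= 0 || cfg$adj_p > 1 || cfg$cox_p <= 0 || cfg$cox_p > 1)
    stop("p-value thresholds must lie in (0,1]")
  if (cfg$subsample_frac <= 0 || cfg$subsample_frac > 1)
    stop("subsample_frac must lie in (0,1]")
  if (any(cfg$pac_window < 0) || any(cfg$pac_window > 1) ||
      cfg$pac_window[1] >= cfg$pac_window[2])
    stop("invalid PAC window")
  if (cfg$maxstat_window[1] >= cfg$maxstat_window[2])
    stop("invalid maxstat window")
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration (lossless JSON round-trip)
#'
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @return `read_pipeline_config()` returns the reconstructed
#'   `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

#' Run the full signature derivation chain
#'
#' Executes, in order: preprocessing (FPKM to TPM, log2, batch correction
#' when batch labels are present), consensus clustering of samples on the
#' signature genes (TLS clusters), moderated-t DEGs between the clusters,
#' consensus clustering of samples on those DEGs (gene clusters), a second
#' DEG pass between gene clusters, univariate Cox screening of the selected
#' genes, PCA score fitting and scoring, and maxstat dichotomization with a
#' log-rank comparison of the high/low groups. If a mutation table is
#' supplied, per-sample TMB is computed and crossed with the score groups.
#'
#' When PAC chooses more than two clusters, the DEG stages compare the two
#' largest clusters (with a warning).
#'
#' @param expression an [expression_matrix()] (FPKM, TPM or logTPM).
#' @param clinical clinical `data.frame` (`sample_id`, `time`, `event`, ...).
#' @param signature_genes gene ids defining the signature block (default: the
#'   packaged 23-gene TLS signature).
#' @param config a [pipeline_config()].
#' @param mutations optional MAF-like mutation `data.frame`.
#' @param out_dir optional directory: every stage then writes a TSV artifact
#'   plus a JSON provenance sidecar (input hashes, thresholds, seed,
#'   package version).
#' @return A list of stage artifacts: `preprocessed`, `tls_clusters`,
#'   `deg_tls`, `gene_clusters`, `deg_gene`, `cox_screen`,
#'   `prognostic_genes`, `model`, `scores` (dichotomized), `logrank`, and
#'   (with mutations) `tmb` and `tmb_strata`.
#' @export
run_derivation <- function(expression, clinical, signature_genes = NULL,
                           config = pipeline_config(), mutations = NULL,
                           out_dir = NULL) {
  stopifnot(inherits(expression, "expression_matrix"),
            inherits(config, "pipeline_config"))
  clinical <- validate_clinical(clinical)
  if (is.null(signature_genes)) signature_genes <- tls_signature("set")$genes
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- list()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  emit <- function(name, df, extra = list()) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, paste0(name, ".tsv"))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    prov <- c(list(stage = name, output = basename(path),
                   output_md5 = unname(tools::md5sum(path)),
                   seed = config$seed,
                   thresholds = list(adj_p = config$adj_p, cox_p = config$cox_p),
                   package_version = as.character(utils::packageVersion("tlscore"))),
              extra)
    jsonlite::write_json(prov, file.path(out_dir, paste0(name, ".provenance.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(path)
  }
  two_groups <- function(labels) {
    tab <- sort(table(labels), decreasing = TRUE)
    if (length(tab) > 2L)
      warning("more than two clusters; DEG stage compares the two largest")
    keep <- names(tab)[1:2]
    labels[labels %in% keep]
  }

  m <- stage("preprocess", {
    x <- expression
    if (x$unit == "FPKM") x <- fpkm_to_tpm(x)
    if (x$unit == "TPM") x <- log_transform(x)
    if (!is.null(x$batch) && length(unique(x$batch)) > 1L)
      x <- combat_correct(x)
    x
  })
  art$preprocessed <- m
  emit("preprocessed_expression",
       data.frame(gene_id = rownames(m$values), m$values, check.names = FALSE))

  sig_present <- intersect(signature_genes, rownames(m$values))
  if (length(sig_present) < 3L) stop("stage 'tls_cluster' failed: <3 signature genes present")
  art$tls_clusters <- stage("tls_cluster",
    consensus_cluster(m, features = sig_present, k_range = config$k_range,
                      n_reps = config$n_reps,
                      subsample_frac = config$subsample_frac,
                      seed = config$seed, method = config$cluster_method,
                      pac_window = config$pac_window))
  emit("tls_clusters",
       data.frame(sample_id = names(art$tls_clusters$labels),
                  tls_cluster = paste0("TLScluster",
                                       LETTERS[art$tls_clusters$labels])),
       list(chosen_k = art$tls_clusters$chosen_k,
            pac = as.list(art$tls_clusters$pac)))

  lab1 <- two_groups(art$tls_clusters$labels)
  art$deg_tls <- stage("deg_tls", {
    sub <- subset_expression(m, samples = names(lab1))
    moderated_t(sub, lab1, adj_threshold = config$adj_p)
  })
  emit("deg_tls", art$deg_tls,
       list(d0 = attr(art$deg_tls, "d0"), s0_2 = attr(art$deg_tls, "s0_2")))
  degs1 <- art$deg_tls$gene_id[art$deg_tls$selected]
  if (length(degs1) < 10L)
    stop("stage 'deg_tls' failed: only ", length(degs1),
         " DEGs at adjusted p < ", config$adj_p)

  art$gene_clusters <- stage("gene_cluster",
    consensus_cluster(m, features = degs1, k_range = config$k_range,
                      n_reps = config$n_reps,
                      subsample_frac = config$subsample_frac,
                      seed = config$seed + 1L, method = config$cluster_method,
                      pac_window = config$pac_window))
  emit("gene_clusters",
       data.frame(sample_id = names(art$gene_clusters$labels),
                  gene_cluster = paste0("geneCluster",
                                        LETTERS[art$gene_clusters$labels])),
       list(chosen_k = art$gene_clusters$chosen_k,
            pac = as.list(art$gene_clusters$pac)))

  lab2 <- two_groups(art$gene_clusters$labels)
  art$deg_gene <- stage("deg_gene", {
    sub <- subset_expression(m, samples = names(lab2))
    moderated_t(sub, lab2, adj_threshold = config$adj_p)
  })
  emit("deg_gene", art$deg_gene)
  degs2 <- art$deg_gene$gene_id[art$deg_gene$selected]
  if (length(degs2) < 3L)
    stop("stage 'deg_gene' failed: only ", length(degs2), " DEGs")

  art$cox_screen <- stage("cox_screen", {
    common <- intersect(colnames(m$values), clinical$sample_id)
    cl <- clinical[match(common, clinical$sample_id), ]
    X <- t(m$values[degs2, common, drop = FALSE])
    cox_screen(cl$time, cl$event, X, p_threshold = config$cox_p)
  })
  emit("cox_screen", art$cox_screen)
  prog <- art$cox_screen$covariate[art$cox_screen$keep]
  if (length(prog) < 3L)
    stop("stage 'cox_screen' failed: only ", length(prog),
         " prognostic genes at p < ", config$cox_p)
  art$prognostic_genes <- prog
  favorable <- art$cox_screen$covariate[art$cox_screen$keep &
                                        art$cox_screen$hr < 1]

  art$model <- stage("fit_score",
    fit_score_model(m, prognostic_genes = prog, favorable_genes = favorable))
  raw_scores <- stage("score", score_samples(art$model, m))
  art$scores <- stage("dichotomize",
    dichotomize(raw_scores, clinical, quantile_window = config$maxstat_window))
  art$logrank <- attr(art$scores, "logrank")
  emit("tlsscore", art$scores,
       list(cutpoint = attr(art$scores, "cutpoint")$cutpoint,
            logrank_chi2 = art$logrank$chi2, logrank_p = art$logrank$p))

  if (!is.null(mutations)) {
    art$tmb <- stage("tmb",
      tmb_from_maf(mutations, samples = art$scores$sample_id))
    art$tmb_strata <- stage("tmb_strata",
      score_tmb_strata(art$scores, art$tmb, clinical))
    emit("tmb_strata", art$tmb_strata,
         list(pearson_r = attr(art$tmb_strata, "pearson")$r,
              pearson_p = attr(art$tmb_strata, "pearson")$p))
  }
  art$config <- config
  art
}

#' Per-sample tumor mutational burden from a MAF-like table
#'
#' Counts qualifying mutations per sample and divides by the captured exome
#' size. By default only non-silent classifications qualify (Silent, Intron,
#' UTR, Flank, IGR and RNA records are excluded); unknown classification
#' strings are excluded too unless `count_unknown = TRUE`, and are reported
#' with a message either way.
#'
#' @param mutations `data.frame` with `Tumor_Sample_Barcode`,
#'   `Variant_Classification` columns.
#' @param samples sample ids to report (samples without rows get TMB 0);
#'   defaults to the samples present in the table.
#' @param exome_mb captured exome size in megabases (default 38; use 1 for
#'   raw counts).
#' @param nonsynonymous_only if `FALSE`, count every row.
#' @param count_unknown whether unrecognized classification strings qualify.
#' @return Named numeric vector of mutations per megabase.
#' @export
tmb_from_maf <- function(mutations, samples = NULL, exome_mb = 38,
                         nonsynonymous_only = TRUE, count_unknown = FALSE) {
  if (is.null(samples)) samples <- unique(mutations$Tumor_Sample_Barcode)
  nonsyn <- c("Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
              "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del",
              "In_Frame_Ins", "Splice_Site", "Translation_Start_Site")
  silent <- c("Silent", "Intron", "3'UTR", "5'UTR", "3'Flank", "5'Flank",
              "IGR", "RNA")
  cls <- mutations$Variant_Classification
  if (nonsynonymous_only) {
    unknown <- setdiff(unique(cls), c(nonsyn, silent))
    if (length(unknown))
      message("unknown classification(s) ",
              if (count_unknown) "counted: " else "excluded: ",
              paste(unknown, collapse = ", "))
    qualify <- cls %in% nonsyn | (count_unknown & cls %in% unknown)
  } else {
    qualify <- rep(TRUE, length(cls))
  }
  counts <- table(factor(mutations$Tumor_Sample_Barcode[qualify],
                         levels = samples))
  stats::setNames(as.numeric(counts) / exome_mb, samples)
}

#' Specific lysis percentage
#'
#' `100 * (test - spontaneous) / (maximal - spontaneous)`.
#'
#' @param test,spontaneous,maximal release measurements (vectors recycle).
#' @return Percent specific lysis.
#' @export
specific_lysis <- function(test, spontaneous, maximal) {
  if (any(maximal <= spontaneous))
    stop("maximal release must exceed spontaneous release")
  (test - spontaneous) / (maximal - spontaneous) * 100
}

#' Tumor volume from caliper measurements
#'
#' `TV = length * width^2 * 0.5` (mm^3).
#'
#' @param length,width tumor dimensions in mm.
#' @return Volume in mm^3.
#' @export
tumor_volume <- function(length, width) {
  if (any(length < 0) || any(width < 0)) stop("dimensions must be non-negative")
  length * width^2 * 0.5
}
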