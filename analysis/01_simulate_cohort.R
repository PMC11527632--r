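#!/usr/bin/env Rscript
# Simulate the study inputs: a three-batch bulk meta-cohort with two latent
# TLS states, a matched MAF-like mutation table whose burden declines with
# the latent score, and a single-cell matrix with a module-enriched T/NK-like
# type. Everything downstream (02-04) reads the files written here.

suppressMessages(library(tlscore))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 1L

spec <- cohort_spec(seed = seed)   # n=300, G=1000, delta=2, 3 batches
coh <- generate_bulk_cohort(spec)
maf <- generate_mutation_table(spec, coh$truth)

# FPKM-like export exercises the FPKM -> TPM -> log2 path in 02
fpkm <- as_fpkm_like(coh$expression, seed = seed)
write_expression_tsv(fpkm, file.path(out, "expression_fpkm.tsv"))
write_clinical_tsv(coh$clinical, file.path(out, "clinical.tsv"))
write.table(data.frame(sample_id = names(coh$truth$batch),
                       batch = coh$truth$batch,
                       latent_state = coh$truth$latent_state,
                       latent_score = coh$truth$latent_score),
            file.path(out, "ground_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(coh$truth$signature_gene_ids, file.path(out, "signature_genes.txt"))
write.table(maf, file.path(out, "mutations.maf.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cells <- generate_single_cell(
  n_cells = 500, n_genes = 600,
  cell_type_props = c(tnk = 0.25, b = 0.25, myeloid = 0.2, tumor = 0.3),
  module_genes = paste0("TLS", 1:23), enriched_type = "tnk",
  seed = seed, enrichment = 4, qc_violation_frac = 0.1)
write_cell_mtx(cells, file.path(out, "single_cell"))
write.table(data.frame(cell_id = rownames(cells$counts),
                       cell_type = cells$cell_type,
                       qc_violation = attr(cells, "qc_violation")),
            file.path(out, "single_cell/cell_metadata.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("bulk cohort: %d samples x %d genes, %d batches, %d events\n",
            spec$n_samples, spec$n_genes, spec$n_batches,
            sum(coh$clinical$event)))
cat(sprintf("mutation table: %d records across %d samples\n",
            nrow(maf), length(unique(maf$Tumor_Sample_Barcode))))
cat(sprintf("single cell: %d cells x %d genes (%d planted QC violators)\n",
            nrow(cells$counts), ncol(cells$counts),
            sum(attr(cells, "qc_violation") != "none")))
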