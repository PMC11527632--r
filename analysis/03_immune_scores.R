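#!/usr/bin/env Rscript
# Immune characterization of the derived score groups: ssGSEA over a small
# synthetic cell-infiltration collection plus ESTIMATE-style stromal/immune/
# purity scores, compared between the high and low score groups.

suppressMessages(library(tlscore))

data_dir <- "results/data"
deriv <- "results/derivation"
out <- "results/immune"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

expr <- read_expression_tsv(file.path(deriv, "preprocessed_expression.tsv"),
                            unit = "logTPM")
scores <- read.table(file.path(deriv, "tlsscore.tsv"), header = TRUE,
                     sep = "\t", stringsAsFactors = FALSE)
signature <- readLines(file.path(data_dir, "signature_genes.txt"))

# synthetic demo collection: the signature block plus random background sets
set.seed(1)
bg <- setdiff(rownames(expr$values), signature)
sets <- c(list(gene_set("tls_signature", signature, "signature")),
          lapply(1:5, function(i)
            gene_set(paste0("background_", i),
                     sample(bg, 40), "background")))
es <- ssgsea(expr, sets, alpha = 0.25, normalize = TRUE)
write.table(data.frame(sample_id = rownames(es), es, check.names = FALSE),
            file.path(out, "ssgsea_scores.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

est <- estimate_scores(expr,
                       stromal_set = gene_set("stromal_demo", sample(bg, 50)),
                       immune_set = gene_set("immune_demo", signature))
write.table(est, file.path(out, "estimate_scores.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

grp <- scores$group[match(est$sample_id, scores$sample_id)]
for (col in c("immune", "estimate", "purity")) {
  cmp <- compare_groups(est[[col]], grp, test = "wilcoxon")
  cat(sprintf("%-9s high vs low: medians %.3f / %.3f, Wilcoxon p = %.3g\n",
              col, median(est[[col]][grp == "high"]),
              median(est[[col]][grp == "low"]), cmp$p))
}
sig_es <- es[, "tls_signature"]
cat(sprintf("signature ssGSEA vs TLSscore: r = %.3f\n",
            cor(sig_es, scores$tlsscore[match(rownames(es),
                                              scores$sample_id)])))
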