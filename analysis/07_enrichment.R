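#!/usr/bin/env Rscript

# Step 7 — functional enrichment of the co-expressed genes.
#
# Hypergeometric over-representation of the non-TF genes linked to any
# family TF, against the background of all expressed genes (TPM >= 1
# in at least one sample), Benjamini-Hochberg corrected at 0.05.

suppressMessages(library(cogcn))

in_dir <- "results/inputs"
out_dir <- "results/tables"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

ex <- read_expression_matrix(file.path(in_dir, "expression_tpm.tsv"),
                             file.path(in_dir, "sample_map.tsv"))
filtered <- filter_low_expression(ex$tpm)
truth <- read_expression_truth(file.path(in_dir, "expression_truth.json"))
tf_ids <- intersect(truth$tf_ids, rownames(filtered))
network <- build_edges(filtered, tf_ids, pcc_min = 0.9)

edges <- network$edges
partners <- unique(c(edges$gene2[edges$gene1 %in% tf_ids],
                     edges$gene1[edges$gene2 %in% tf_ids]))
study <- setdiff(partners, tf_ids)
background <- rownames(filtered)
cat(sprintf("study: %d co-expressed non-TF genes; background: %d expressed genes\n",
            length(study), length(background)))

term_map <- read_term_map(file.path(in_dir, "term_map.tsv"))
results <- enrich(study, background, term_map, alpha = 0.05)
write.table(results, file.path(out_dir, "enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("%d terms tested, %d significant (BH-adjusted p < 0.05)\n",
            nrow(results), sum(results$significant)))
print(utils::head(results[, c("term_id", "k", "K", "p_value", "adjusted_p",
                              "significant")], 5), row.names = FALSE)
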