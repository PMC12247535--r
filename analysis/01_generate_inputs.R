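#!/usr/bin/env Rscript

# Step 1 — generate the synthetic study inputs.
#
# Emulates the study design: a six-step NaCl gradient (T0-T150, three
# replicates), a TF family of 30 genes planted in five co-expression
# modules among 500 genes, a toy multi-chromosome genome carrying the
# family's gene models with motif-seeded promoters, homology hit tables
# whose intended survivors are the family members, random protein
# sequences and a module-structured functional term map. Every
# generator records its ground truth so the later steps can be checked
# against an answer key.

suppressMessages(library(cogcn))

seed <- 42
in_dir <- "results/inputs"
dir.create(in_dir, recursive = TRUE, showWarnings = FALSE)

sim <- generate_expression(n_genes = 500, n_tf = 30, n_modules = 5,
                           reps = 3, noise_sd = 0.1, seed = seed)
expr_files <- write_expression_files(sim, in_dir)
cat(sprintf("expression: %d genes x %d samples; %d TFs in %d modules, %d baits, %d low-expression\n",
            nrow(sim$tpm), ncol(sim$tpm), length(sim$truth$tf_ids),
            length(unique(sim$truth$module_assignments)),
            length(sim$truth$bait_ids), length(sim$truth$low_expression_ids)))

gen <- generate_genome(n_chrom = 3, genes_per_chrom = 10, seed = seed + 1)
gen$annotation <- gen$annotation[seq_len(30), , drop = FALSE]
id_map <- setNames(sim$truth$tf_ids, gen$annotation$gene_id)
gen$truth <- gen$truth[gen$truth$gene_id %in% names(id_map), , drop = FALSE]
gen$truth$gene_id <- unname(id_map[gen$truth$gene_id])
gen$annotation$gene_id <- unname(id_map[gen$annotation$gene_id])
genome_files <- write_genome_files(gen, in_dir)
cat(sprintf("genome: %d chromosomes, %d gene models, %d planted promoter motifs\n",
            length(gen$genome), nrow(gen$annotation), nrow(gen$truth)))

decoys <- setdiff(rownames(sim$tpm), sim$truth$tf_ids)[1:20]
hits <- generate_hit_tables(sim$truth$tf_ids, decoys, seed = seed + 2)
write_hit_tables(hits, in_dir)
cat(sprintf("hit tables: %d true family members, %d decoys over four failure modes\n",
            length(hits$truth$survivors), length(decoys)))

prots <- random_protein_sequences(sim$truth$tf_ids, seed = seed + 3)
writeLines(paste0(">", names(prots), "\n", unname(prots)),
           file.path(in_dir, "proteins.faa"))

term_map <- synthetic_term_map(sim$truth, rownames(sim$tpm), seed = seed + 4)
write.table(term_map, file.path(in_dir, "term_map.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("term map: %d gene-term links over %d terms\n",
            nrow(term_map), length(unique(term_map$term_id))))
cat("inputs written under", in_dir, "\n")
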