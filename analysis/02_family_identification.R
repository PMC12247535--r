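#!/usr/bin/env Rscript

# Step 2 — identify the TF family and rename members by position.
#
# Intersects the HMM-profile hits with identity-filtered BLAST hits
# (identity >= 30%, e-value <= 1e-5, both inclusive) and numbers the
# survivors TCP1..TCPn along the genome (natural chromosome order,
# then start coordinate).

suppressMessages(library(cogcn))

in_dir <- "results/inputs"
out_dir <- "results/tables"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

hmm <- read_hmmer_tbl(file.path(in_dir, "hmm_hits.tbl"))
blast <- read_blast_outfmt6(file.path(in_dir, "blast_hits.tsv"))
candidates <- intersect_candidates(hmm, blast)
truth <- jsonlite::read_json(file.path(in_dir, "hits_truth.json"),
                             simplifyVector = TRUE)
cat(sprintf("%d candidates survive the HMM x BLAST intersection (answer key: %d; exact match: %s)\n",
            length(candidates), length(truth$survivors),
            setequal(candidates, truth$survivors)))

annotation <- read_gene_annotation(file.path(in_dir, "genes.gff3"))
renaming <- rename_by_position(candidates, annotation, prefix = "TCP")
write.table(renaming, file.path(out_dir, "family_members.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("renamed %s..%s across %d chromosomes -> %s\n",
            renaming$family_name[1], renaming$family_name[nrow(renaming)],
            length(unique(renaming$chrom)),
            file.path(out_dir, "family_members.tsv")))
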