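#!/usr/bin/env Rscript

# Step 3 — physicochemical profile of the family proteins.
#
# Length, average-mass molecular weight, Bjellqvist-table pI,
# Guruprasad instability index (unstable above 40), Ikai aliphatic
# index and Kyte-Doolittle GRAVY for every family protein.

suppressMessages(library(cogcn))

prots <- Biostrings::readAAStringSet("results/inputs/proteins.faa")
props <- protein_properties(prots)
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
write.table(props, "results/tables/protein_properties.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("%d proteins: pI %.2f-%.2f (%d acidic, pI < 7)\n",
            nrow(props), min(props$pI), max(props$pI), sum(props$pI < 7)))
cat(sprintf("instability index %.2f-%.2f; %d/%d predicted unstable (II > 40)\n",
            min(props$instability_index), max(props$instability_index),
            sum(props$stability == "unstable"), nrow(props)))
cat(sprintf("aliphatic index %.2f-%.2f (mean %.2f); %d hydrophilic (GRAVY < 0)\n",
            min(props$aliphatic_index), max(props$aliphatic_index),
            mean(props$aliphatic_index), sum(props$gravy < 0)))
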