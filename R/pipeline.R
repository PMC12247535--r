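# End-to-end orchestration: one config object drives family
# identification, protein properties, promoter/CRE scanning,
# expression filtering and classification, network construction and
# enrichment, writing every stage output plus a reproducibility
# manifest under one output directory.

#' Build a validated pipeline configuration
#'
#' All thresholds default to the study's printed values: BLAST identity
#' 30%, e-value 1e-5, TPM floor 1, PCC threshold 0.9, significance
#' alpha 0.05, promoter length 2000 bp.
#'
#' @param blast_path,hmm_path homology hit tables (outfmt-6 TSV /
#'   HMMER tabular).
#' @param protein_fasta_path protein FASTA of candidate sequences.
#' @param genome_fasta_path,gff3_path genome sequence and annotation.
#' @param expression_path,sample_map_path TPM matrix and
#'   sample-treatment map TSVs.
#' @param motif_path CRE motif table TSV (NULL: shipped default
#'   catalog).
#' @param term_map_path gene-to-term TSV for enrichment (optional).
#' @param out_dir output directory.
#' @param identity_min,evalue_max,tpm_min,pcc_min,rel_tol,alpha,upstream
#'   stage thresholds.
#' @param pair_scope edge scope for [build_edges()].
#' @param family_prefix prefix for positional renaming.
#' @param seed seed recorded in the manifest (the pipeline stages are
#'   deterministic; the seed matters only to the generators that
#'   produced synthetic inputs).
#' @return a `cogcn_config` list.
#' @export
pipeline_config <- function(blast_path, hmm_path, protein_fasta_path,
                            genome_fasta_path, gff3_path,
                            expression_path, sample_map_path,
                            motif_path = NULL, term_map_path = NULL,
                            out_dir = "cogcn_out",
                            identity_min = 30, evalue_max = 1e-5,
                            tpm_min = 1, pcc_min = 0.9, rel_tol = 0.1,
                            alpha = 0.05, upstream = 2000,
                            pair_scope = c("tf_vs_nontf", "tf_vs_all"),
                            family_prefix = "TCP", seed = 42) {
  pair_scope <- match.arg(pair_scope)
  checks <- c(identity_min >= 0 && identity_min <= 100,
              evalue_max > 0, tpm_min >= 0,
              pcc_min >= -1 && pcc_min <= 1, rel_tol >= 0,
              alpha > 0 && alpha < 1, upstream >= 1)
  if (!all(checks)) stop("config threshold out of documented range", call. = FALSE)
  structure(list(
    blast_path = blast_path, hmm_path = hmm_path,
    protein_fasta_path = protein_fasta_path,
    genome_fasta_path = genome_fasta_path, gff3_path = gff3_path,
    expression_path = expression_path, sample_map_path = sample_map_path,
    motif_path = motif_path, term_map_path = term_map_path,
    out_dir = out_dir, identity_min = identity_min, evalue_max = evalue_max,
    tpm_min = tpm_min, pcc_min = pcc_min, rel_tol = rel_tol, alpha = alpha,
    upstream = upstream, pair_scope = pair_scope,
    family_prefix = family_prefix, seed = seed
  ), class = "cogcn_config")
}

# internal: run one stage with an informative failure message
run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Stages, in order: candidate identification (HMM x BLAST
#' intersection) and positional renaming; protein physicochemical
#' properties; promoter extraction and CRE scan/summary; expression
#' filtering, treatment means and pattern classification; co-expression
#' network with bait selection, BFS levels and hub statistics;
#' hypergeometric enrichment of the co-expressed non-TF genes against
#' the expressed background. Every stage writes a TSV under
#' `config$out_dir`; the returned manifest records parameters, input
#' checksums, per-stage row counts and output checksums. Identical
#' config and inputs reproduce identical output and manifest checksums.
#'
#' @param config a `cogcn_config` from [pipeline_config()].
#' @return the manifest (also written as `manifest.json`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "cogcn_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(); row_counts <- integer()
  record_output <- function(name, path, rows) {
    outputs[[name]] <<- path
    row_counts[[name]] <<- rows
    path
  }
  save_tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    record_output(name, path, nrow(df))
  }

  # stage 1: family identification
  family <- run_stage("family_id", {
    hmm <- read_hmmer_tbl(config$hmm_path)
    blast <- read_blast_outfmt6(config$blast_path)
    candidates <- intersect_candidates(hmm, blast,
                                       identity_min = config$identity_min,
                                       evalue_max = config$evalue_max)
    annotation <- read_gene_annotation(config$gff3_path)
    renaming <- rename_by_position(candidates, annotation,
                                   prefix = config$family_prefix)
    save_tsv(renaming, "family_members.tsv")
    list(candidates = candidates, renaming = renaming,
         annotation = annotation)
  })

  # stage 2: protein properties
  run_stage("protein_properties", {
    prots <- Biostrings::readAAStringSet(config$protein_fasta_path)
    names(prots) <- sub("\\s.*$", "", names(prots))
    keep <- intersect(names(prots), family$candidates)
    props <- protein_properties(prots[keep])
    save_tsv(props, "protein_properties.tsv")
  })

  # stage 3: promoters and CREs
  cre <- run_stage("promoter_cre", {
    genome <- read_genome_fasta(config$genome_fasta_path)
    motifs <- if (is.null(config$motif_path)) default_motif_table()
              else read_motif_table(config$motif_path)
    promoters <- extract_promoters(genome, family$annotation,
                                   upstream = config$upstream,
                                   gene_ids = family$candidates)
    matches <- scan_cres(promoters, motifs)
    cats <- categorize_cres(matches)
    save_tsv(matches, "cre_matches.tsv")
    save_tsv(cats$per_gene, "cre_per_gene.tsv")
    save_tsv(cats$summary, "cre_summary.tsv")
    cats
  })

  # stage 4: expression
  expr <- run_stage("expression", {
    ex <- read_expression_matrix(config$expression_path,
                                 config$sample_map_path)
    filtered <- filter_low_expression(ex$tpm, tpm_min = config$tpm_min)
    means <- treatment_means(filtered, ex$treatments)
    labels <- classify_patterns(means, rel_tol = config$rel_tol)
    save_tsv(data.frame(gene_id = rownames(filtered), filtered,
                        check.names = FALSE), "expression_filtered.tsv")
    save_tsv(data.frame(gene_id = rownames(means), means,
                        check.names = FALSE), "treatment_means.tsv")
    save_tsv(labels, "pattern_labels.tsv")
    list(filtered = filtered, means = means, labels = labels)
  })

  # stage 5: co-expression network
  net <- run_stage("network", {
    tf_ids <- intersect(family$candidates, rownames(expr$filtered))
    network <- build_edges(expr$filtered, tf_ids, pcc_min = config$pcc_min,
                           pair_scope = config$pair_scope)
    baits <- select_bait_genes(expr$means, rel_tol = config$rel_tol)
    baits_in <- intersect(baits, network$nodes$gene_id)
    if (length(baits_in) > 0) {
      network <- assign_levels_bfs(network, baits_in)
    }
    hubs <- hub_statistics(network)
    export_network(network, file.path(out_dir, "network_edges.tsv"),
                   format = "edgelist")
    record_output("network_edges.tsv", file.path(out_dir, "network_edges.tsv"),
                  nrow(network$edges))
    save_tsv(data.frame(gene_id = baits), "bait_genes.tsv")
    save_tsv(hubs, "hub_statistics.tsv")
    list(network = network, baits = baits, hubs = hubs)
  })

  # stage 6: enrichment (optional: needs a term map)
  if (!is.null(config$term_map_path)) {
    run_stage("enrichment", {
      term_map <- read_term_map(config$term_map_path)
      background <- rownames(expr$filtered)
      edges <- net$network$edges
      tf_ids <- intersect(family$candidates, rownames(expr$filtered))
      partners <- unique(c(edges$gene2[edges$gene1 %in% tf_ids],
                           edges$gene1[edges$gene2 %in% tf_ids]))
      study <- setdiff(partners, tf_ids)
      results <- enrich(study, background, term_map, alpha = config$alpha)
      save_tsv(results, "enrichment.tsv")
    })
  }

  manifest <- list(
    package = "cogcn",
    version = as.character(utils::packageVersion("cogcn")),
    parameters = unclass(config)[c("identity_min", "evalue_max", "tpm_min",
                                   "pcc_min", "rel_tol", "alpha", "upstream",
                                   "pair_scope", "family_prefix", "seed")],
    inputs = lapply(Filter(Negate(is.null),
                           unclass(config)[c("blast_path", "hmm_path",
                                             "protein_fasta_path",
                                             "genome_fasta_path", "gff3_path",
                                             "expression_path",
                                             "sample_map_path", "motif_path",
                                             "term_map_path")]),
                    file_md5),
    stages = lapply(stats::setNames(names(outputs), names(outputs)),
                    function(nm) list(rows = row_counts[[nm]],
                                      md5 = file_md5(outputs[[nm]])))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' One-command synthetic demonstration run
#'
#' Generates a coherent synthetic input set (expression matrix with
#' planted modules, toy genome whose gene models are identified with
#' the matrix's TF genes, hit tables whose intended survivors are those
#' same TFs, random protein sequences and a module-based term map),
#' then runs the full pipeline on it. Deterministic: the same seed
#' yields byte-identical stage outputs.
#'
#' @param out_dir output directory (inputs under `inputs/`, stage
#'   outputs under `results/`).
#' @param seed RNG seed (default 42).
#' @param n_genes,n_tf,n_modules,reps,noise_sd forwarded to
#'   [generate_expression()].
#' @return list with the pipeline manifest and the generator truths.
#' @export
run_demo <- function(out_dir, seed = 42, n_genes = 500, n_tf = 30,
                     n_modules = 5, reps = 3, noise_sd = 0.1) {
  in_dir <- file.path(out_dir, "inputs")
  dir.create(in_dir, recursive = TRUE, showWarnings = FALSE)

  sim <- generate_expression(n_genes = n_genes, n_tf = n_tf,
                             n_modules = n_modules, reps = reps,
                             noise_sd = noise_sd, seed = seed)
  expr_files <- write_expression_files(sim, in_dir)

  # genome whose genes are the TF family members, in chromosomal order
  n_chrom <- 3
  genes_per_chrom <- ceiling(n_tf / n_chrom)
  gen <- generate_genome(n_chrom = n_chrom, genes_per_chrom = genes_per_chrom,
                         seed = seed + 1)
  gen$annotation <- gen$annotation[seq_len(n_tf), , drop = FALSE]
  id_map <- stats::setNames(sim$truth$tf_ids, gen$annotation$gene_id)
  keep_truth <- gen$truth$gene_id %in% names(id_map)
  gen$truth <- gen$truth[keep_truth, , drop = FALSE]
  gen$truth$gene_id <- unname(id_map[gen$truth$gene_id])
  gen$annotation$gene_id <- unname(id_map[gen$annotation$gene_id])
  genome_files <- write_genome_files(gen, in_dir)

  decoys <- setdiff(rownames(sim$tpm), sim$truth$tf_ids)[1:20]
  hits <- generate_hit_tables(sim$truth$tf_ids, decoys, seed = seed + 2)
  hit_files <- write_hit_tables(hits, in_dir)

  prots <- random_protein_sequences(sim$truth$tf_ids, seed = seed + 3)
  protein_path <- file.path(in_dir, "proteins.faa")
  writeLines(paste0(">", names(prots), "\n", unname(prots)), protein_path)

  term_map <- synthetic_term_map(sim$truth, rownames(sim$tpm), seed = seed + 4)
  term_path <- file.path(in_dir, "term_map.tsv")
  utils::write.table(term_map, term_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  config <- pipeline_config(
    blast_path = hit_files[["blast"]], hmm_path = hit_files[["hmm"]],
    protein_fasta_path = protein_path,
    genome_fasta_path = genome_files[["fasta"]],
    gff3_path = genome_files[["gff3"]],
    expression_path = expr_files[["matrix"]],
    sample_map_path = expr_files[["sample_map"]],
    term_map_path = term_path,
    out_dir = file.path(out_dir, "results"),
    seed = seed
  )
  manifest <- run_pipeline(config)
  list(manifest = manifest, expression_truth = sim$truth,
       genome_truth = gen$truth, hits_truth = hits$truth, config = config)
}
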