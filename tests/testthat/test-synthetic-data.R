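test_that("expression generation is deterministic and validated", {
  a <- generate_expression(n_genes = 100, n_tf = 10, seed = 5,
                           nontf_per_module = 5)
  b <- generate_expression(n_genes = 100, n_tf = 10, seed = 5,
                           nontf_per_module = 5)
  expect_identical(a$tpm, b$tpm)
  expect_identical(a$truth, b$truth)
  c <- generate_expression(n_genes = 100, n_tf = 10, seed = 6,
                           nontf_per_module = 5)
  expect_false(identical(a$tpm, c$tpm))
  expect_error(generate_expression(n_genes = 10, n_tf = 20), "n_tf < n_genes")
  expect_error(generate_expression(noise_sd = -0.1), "non-negative")
  expect_error(generate_expression(n_genes = 0), "positive")
})

test_that("noise-free modules correlate perfectly pair by pair", {
  sim <- generate_expression(n_genes = 80, n_tf = 10, noise_sd = 0, seed = 5,
                             nontf_per_module = 4)
  pairs <- planted_module_pairs(sim$truth)
  for (i in seq_len(min(nrow(pairs), 40))) {
    expect_equal(pcc(sim$tpm[pairs$gene1[i], ], sim$tpm[pairs$gene2[i], ]), 1)
  }
})

test_that("planted structure honours its own invariants", {
  sim <- generate_expression(n_genes = 150, n_tf = 10, seed = 13,
                             nontf_per_module = 6)
  truth <- sim$truth
  expect_true(all(sim$tpm >= 0))
  # low-expression genes sit below 1 in every sample
  expect_true(all(sim$tpm[truth$low_expression_ids, ] < 1))
  # every module carries >= 1 TF and >= 3 non-TF genes
  for (m in unique(truth$module_assignments)) {
    members <- names(truth$module_assignments)[truth$module_assignments == m]
    expect_gte(length(intersect(members, truth$tf_ids)), 1)
    expect_gte(length(setdiff(members, truth$tf_ids)), 3)
  }
  # noiseless bait archetype: T0 maximum, non-increasing across treatments
  arch <- synth_archetypes()
  bait_arch <- arch["down", ]
  expect_equal(unname(which.max(bait_arch)), 1)
  expect_true(all(diff(bait_arch) <= 0))
  # bait truth = all genes of down-archetype modules
  down_modules <- names(truth$module_archetype)[truth$module_archetype == "down"]
  expect_setequal(truth$bait_ids,
                  names(truth$module_assignments)[
                    truth$module_assignments %in% down_modules])
})

test_that("the four directional pattern classes are all planted", {
  sim <- generate_expression(seed = 42)
  expect_setequal(intersect(unique(sim$truth$pattern_labels), PATTERN_CLASSES),
                  PATTERN_CLASSES)
})

test_that("genome generation is deterministic down to the bytes", {
  a <- generate_genome(n_chrom = 1, genes_per_chrom = 3, seed = 2)
  b <- generate_genome(n_chrom = 1, genes_per_chrom = 3, seed = 2)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$truth, b$truth)
  dir_a <- withr::local_tempdir(); dir_b <- withr::local_tempdir()
  fa <- write_genome_files(a, dir_a); fb <- write_genome_files(b, dir_b)
  expect_identical(readLines(fa[["fasta"]]), readLines(fb[["fasta"]]))
  expect_identical(readLines(fa[["gff3"]]), readLines(fb[["gff3"]]))
})

test_that("each chromosome leads with a truncation-testing gene", {
  gen <- generate_genome(n_chrom = 2, genes_per_chrom = 3, seed = 4)
  first <- gen$annotation[!duplicated(gen$annotation$chrom), ]
  expect_true(all(first$start < 2000))
  expect_true(all(first$strand == "+"))
  prom <- extract_promoters(gen$genome, gen$annotation,
                            gene_ids = first$gene_id)
  expect_true(all(Biostrings::width(prom) == first$start - 1))
  # spacing elsewhere leaves full-length promoters
  rest <- gen$annotation[duplicated(gen$annotation$chrom), ]
  prom2 <- extract_promoters(gen$genome, gen$annotation,
                             gene_ids = rest$gene_id)
  expect_true(all(Biostrings::width(prom2) == 2000))
})

test_that("invalid IUPAC motifs abort genome generation", {
  bad <- data.frame(element_name = "bad", iupac_pattern = "ACQT",
                    category = "stress", stringsAsFactors = FALSE)
  expect_error(generate_genome(promoter_motifs = bad), "IUPAC")
})

test_that("hit-table generation is deterministic with disjoint-set checks", {
  ids <- sprintf("t%02d", 1:8); dec <- sprintf("d%02d", 1:6)
  a <- generate_hit_tables(ids, dec, seed = 7)
  b <- generate_hit_tables(ids, dec, seed = 7)
  expect_identical(a, b)
  expect_error(generate_hit_tables(ids, ids[1]), "disjoint")
  # all four decoy fates are exercised
  expect_setequal(unique(a$truth$decoy_fate),
                  c("blast_only", "hmm_only", "low_identity", "high_evalue"))
  # hmm-only decoys never get a BLAST row; blast-only never an HMM row
  hmm_only <- names(a$truth$decoy_fate)[a$truth$decoy_fate == "hmm_only"]
  expect_length(intersect(hmm_only, a$blast$qseqid), 0)
  blast_only <- names(a$truth$decoy_fate)[a$truth$decoy_fate == "blast_only"]
  expect_length(intersect(blast_only, a$hmm$target_name), 0)
})
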