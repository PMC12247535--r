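toy_genome <- function(len = 5000, seed = 31) {
  set.seed(seed)
  g <- Biostrings::DNAStringSet(random_dna(len))
  names(g) <- "chrT"
  g
}

test_that("plus-strand promoters are the upstream window, 1-based closed", {
  g <- toy_genome()
  ann <- data.frame(gene_id = "gA", chrom = "chrT", start = 3001, end = 3600,
                    strand = "+", stringsAsFactors = FALSE)
  p <- extract_promoters(g, ann)
  expect_equal(Biostrings::width(p), 2000)
  expect_equal(as.character(p[[1]]),
               as.character(Biostrings::subseq(g[[1]], 1001, 3000)))
})

test_that("promoters truncate at the chromosome start, never pad", {
  g <- toy_genome()
  ann <- data.frame(gene_id = "gB", chrom = "chrT", start = 501, end = 900,
                    strand = "+", stringsAsFactors = FALSE)
  p <- extract_promoters(g, ann)
  expect_equal(Biostrings::width(p), 500)
  expect_equal(as.character(p[[1]]),
               as.character(Biostrings::subseq(g[[1]], 1, 500)))
})

test_that("minus-strand promoters are downstream in forward coordinates, reverse-complemented", {
  g <- toy_genome()
  ann <- data.frame(gene_id = "gC", chrom = "chrT", start = 1000, end = 1500,
                    strand = "-", stringsAsFactors = FALSE)
  p <- extract_promoters(g, ann)
  expect_equal(Biostrings::width(p), 2000)
  expect_equal(as.character(p[[1]]),
               as.character(Biostrings::reverseComplement(
                 Biostrings::subseq(g[[1]], 1501, 3500))))
  # and it truncates against the chromosome end
  ann$end <- 4000
  expect_equal(Biostrings::width(extract_promoters(g, ann)), 1000)
})

test_that("missing genes or chromosomes raise lookup errors", {
  g <- toy_genome()
  ann <- data.frame(gene_id = "gA", chrom = "chrMissing", start = 3001,
                    end = 3600, strand = "+", stringsAsFactors = FALSE)
  expect_error(extract_promoters(g, ann), "chrMissing")
  ann$chrom <- "chrT"
  expect_error(extract_promoters(g, ann, gene_ids = "ghost"), "ghost")
})

test_that("IUPAC scanning finds exact and degenerate matches at 0-based offsets", {
  motifs <- data.frame(element_name = c("m1", "ebox"),
                       iupac_pattern = c("TGACG", "CANNTG"),
                       category = c("hormone", "growth"),
                       stringsAsFactors = FALSE)
  hits <- scan_cres(c(p = "ATGACGT"), motifs, both_strands = FALSE)
  expect_equal(hits$element_name, "m1")
  expect_equal(hits$offset, 1L)
  hits2 <- scan_cres(c(p = "CACGTG"), motifs[2, ], both_strands = FALSE)
  expect_equal(hits2$offset, 0L)
})

test_that("palindromic sites are reported once per strand", {
  motifs <- data.frame(element_name = "pal", iupac_pattern = "CACGTG",
                       category = "growth", stringsAsFactors = FALSE)
  hits <- scan_cres(c(p = "TTCACGTGTT"), motifs)
  expect_equal(nrow(hits), 2)
  expect_setequal(hits$strand, c("+", "-"))
  expect_equal(unique(hits$offset), 2L)
})

test_that("overlapping occurrences are all counted", {
  motifs <- data.frame(element_name = "rep", iupac_pattern = "AAA",
                       category = "stress", stringsAsFactors = FALSE)
  hits <- scan_cres(c(p = "AAAAA"), motifs, both_strands = FALSE)
  expect_equal(hits$offset, 0:2)
})

test_that("the scanner agrees with a naive per-position matcher on random sequences", {
  motifs <- data.frame(
    element_name = c("a", "b", "c", "d"),
    iupac_pattern = c("TGACG", "CANNTG", "GATGAYRTGR", "WTTSAA"),
    category = "stress", stringsAsFactors = FALSE)
  set.seed(32)
  for (i in 1:6) {
    s <- random_dna(sample(c(200, 1000, 5000), 1))
    hits <- scan_cres(stats::setNames(s, "g"), motifs)
    for (m in seq_len(nrow(motifs))) {
      got <- hits[hits$element_name == motifs$element_name[m], c("offset", "strand")]
      got <- got[order(got$offset, got$strand), , drop = FALSE]
      want <- naive_iupac_scan(s, motifs$iupac_pattern[m])
      expect_equal(unname(as.matrix(got)), unname(as.matrix(want)),
                   ignore_attr = TRUE)
    }
  }
})

test_that("invalid IUPAC letters are rejected", {
  motifs <- data.frame(element_name = "bad", iupac_pattern = "ACGX",
                       category = "stress", stringsAsFactors = FALSE)
  expect_error(scan_cres(c(p = "ACGT"), motifs), "IUPAC")
})

test_that("category shares reproduce published-style element splits", {
  # 38 distinct elements split 10 / 11 / 17
  matches <- data.frame(
    gene_id = "g",
    element_name = paste0("e", 1:38),
    category = rep(c("stress", "hormone", "growth"), c(10, 11, 17)),
    offset = 0L, strand = "+", stringsAsFactors = FALSE)
  out <- categorize_cres(matches)
  expect_equal(out$summary$pct_elements, c(26.3, 28.9, 44.7))
  expect_equal(out$summary$n_elements, c(10L, 11L, 17L))
  expect_equal(sum(out$summary$pct_elements), 100, tolerance = 0.1 / 100)
})

test_that("single-category input takes a 100.0 percent share", {
  matches <- data.frame(gene_id = "g", element_name = c("e1", "e2"),
                        category = "stress", offset = 0L, strand = "+",
                        stringsAsFactors = FALSE)
  out <- categorize_cres(matches)
  expect_equal(out$summary$pct_elements, c(100, 0, 0))
})

test_that("per-gene counts separate the three categories from 'other'", {
  matches <- data.frame(
    gene_id = c("g1", "g1", "g1", "g2"),
    element_name = c("e1", "e1", "e2", "e3"),
    category = c("stress", "stress", "unmapped", "growth"),
    offset = c(0L, 5L, 9L, 2L), strand = "+", stringsAsFactors = FALSE)
  out <- categorize_cres(matches)
  g1 <- out$per_gene[out$per_gene$gene_id == "g1", ]
  expect_equal(g1$stress_count, 2L)
  expect_equal(g1$other_count, 1L)
  expect_equal(g1$total, 2L)  # 'other' excluded from the three-way total
})

test_that("an external category map overrides carried categories", {
  matches <- data.frame(gene_id = "g", element_name = "e1", category = "stress",
                        offset = 0L, strand = "+", stringsAsFactors = FALSE)
  cmap <- data.frame(element_name = "e1", category = "growth",
                     stringsAsFactors = FALSE)
  out <- categorize_cres(matches, category_map = cmap)
  expect_equal(out$per_gene$growth_count, 1L)
  expect_equal(out$per_gene$stress_count, 0L)
})

test_that("the shipped motif catalog parses to the built-in table", {
  path <- system.file("extdata", "cre_motifs.tsv", package = "cogcn")
  expect_identical(read_motif_table(path), default_motif_table())
})

test_that("planted promoter motifs are recovered exactly from the synthetic genome", {
  gen <- generate_genome(n_chrom = 2, genes_per_chrom = 3, seed = 5)
  prom <- extract_promoters(gen$genome, gen$annotation)
  hits <- scan_cres(prom, default_motif_table())
  expect_identical(match_key(hits), match_key(gen$truth))
  # per-gene occurrence counts equal the truth's
  out <- categorize_cres(hits)
  truth_counts <- table(gen$truth$gene_id)
  for (g in names(truth_counts)) {
    row <- out$per_gene[out$per_gene$gene_id == g, ]
    expect_equal(row$total, as.integer(truth_counts[[g]]))
  }
})

test_that("minus-strand planted motifs appear only after reverse-complement extraction", {
  gen <- generate_genome(n_chrom = 1, genes_per_chrom = 4, seed = 8)
  minus <- gen$annotation[gen$annotation$strand == "-", , drop = FALSE]
  skip_if(nrow(minus) == 0)
  row <- minus[1, ]
  planted <- gen$truth[gen$truth$gene_id == row$gene_id, , drop = FALSE]
  skip_if(nrow(planted) == 0)
  prom_rc <- extract_promoters(gen$genome, gen$annotation, gene_ids = row$gene_id)
  hits_rc <- scan_cres(prom_rc, default_motif_table())
  expect_identical(match_key(hits_rc), match_key(planted))
  # naive extraction without reverse-complementing misses the answer key
  fwd <- Biostrings::subseq(gen$genome[[row$chrom]], row$end + 1,
                            min(length(gen$genome[[row$chrom]]), row$end + 2000))
  hits_fwd <- scan_cres(stats::setNames(as.character(fwd), row$gene_id),
                        default_motif_table())
  expect_false(identical(match_key(hits_fwd), match_key(planted)))
})
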