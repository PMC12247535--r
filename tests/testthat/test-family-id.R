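make_blast <- function(ids, pident = 50, evalue = 1e-10) {
  n <- length(ids)
  data.frame(qseqid = ids, sseqid = paste0("ref", seq_len(n)),
             pident = rep_len(pident, n), length = 200, mismatch = 0,
             gapopen = 0, qstart = 1, qend = 200, sstart = 1, send = 200,
             evalue = rep_len(evalue, n), bitscore = 300,
             stringsAsFactors = FALSE)
}
make_hmm <- function(ids) {
  data.frame(target_name = ids, query_name = "TCP", evalue = 1e-20,
             stringsAsFactors = FALSE)
}

test_that("candidate intersection keeps ids in both hit sets", {
  hmm <- make_hmm(c("A", "B", "C"))
  blast <- make_blast(c("B", "C", "D"))
  expect_equal(intersect_candidates(hmm, blast), c("B", "C"))
})

test_that("identity and e-value boundaries are inclusive", {
  hmm <- make_hmm(c("lo", "hi", "ev_ok", "ev_bad"))
  blast <- rbind(make_blast("lo", pident = 29.9),
                 make_blast("hi", pident = 30.0),
                 make_blast("ev_ok", evalue = 1e-5),
                 make_blast("ev_bad", evalue = 2e-5))
  expect_equal(intersect_candidates(hmm, blast), c("ev_ok", "hi"))
})

test_that("a gene with any passing BLAST row survives", {
  hmm <- make_hmm("multi")
  blast <- rbind(make_blast("multi", pident = 20),
                 make_blast("multi", pident = 45),
                 make_blast("multi", evalue = 1))
  expect_equal(intersect_candidates(hmm, blast), "multi")
})

test_that("intersection is commutative in its lists and duplicate-proof", {
  hmm <- make_hmm(c("A", "B"))
  blast <- make_blast(c("B", "C"))
  base <- intersect_candidates(hmm, blast)
  expect_equal(intersect_candidates(make_hmm(c("B", "A", "B")),
                                    rbind(blast, blast)), base)
  # swapping which screen found which id does not change the set
  expect_equal(intersect_candidates(make_hmm(c("B", "C")),
                                    make_blast(c("A", "B"))), "B")
})

test_that("the synthetic hit fixture intersects to its recorded truth", {
  ids <- sprintf("g%05d", 1:26)
  decoys <- sprintf("d%03d", 1:12)
  hits <- generate_hit_tables(ids, decoys, seed = 3)
  dir <- withr::local_tempdir()
  files <- write_hit_tables(hits, dir)
  blast <- read_blast_outfmt6(files[["blast"]])
  hmm <- read_hmmer_tbl(files[["hmm"]])
  expect_equal(intersect_candidates(hmm, blast), hits$truth$survivors)
  # decoys present in only one table, or failing a filter, never survive
  expect_length(intersect(decoys, intersect_candidates(hmm, blast)), 0)
  expect_true(any(blast$pident == 30.0))
})

test_that("malformed hit rows raise format errors naming the line", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.tsv")
  writeLines(c(paste(c("q", "s", "50", rep("1", 8), "300"), collapse = "\t"),
               "q2\ts2\tnot_a_number"), bad)
  expect_error(read_blast_outfmt6(bad), "line 2")
})

test_that("positional renaming follows chromosome, then start", {
  ann <- data.frame(
    gene_id = c("x", "y", "z"),
    chrom = c("chr01", "chr02", "chr01"),
    start = c(500, 50, 100), end = c(600, 150, 200),
    strand = "+", stringsAsFactors = FALSE)
  out <- rename_by_position(c("x", "y", "z"), ann, prefix = "TCP")
  expect_equal(out$gene_id, c("z", "x", "y"))
  expect_equal(out$family_name, c("TCP1", "TCP2", "TCP3"))
})

test_that("chromosome names sort naturally, not lexically", {
  ann <- data.frame(gene_id = c("a", "b", "c"),
                    chrom = c("chr10", "chr09", "chr01"),
                    start = 100, end = 200, strand = "+",
                    stringsAsFactors = FALSE)
  out <- rename_by_position(c("a", "b", "c"), ann)
  expect_equal(out$gene_id, c("c", "b", "a"))
})

test_that("renaming is a stable bijection under input permutation", {
  set.seed(21)
  ann <- data.frame(gene_id = sprintf("g%02d", 1:12),
                    chrom = sample(c("chr1", "chr2", "chr3"), 12, replace = TRUE),
                    start = sample(1e4, 12), end = 2e4, strand = "+",
                    stringsAsFactors = FALSE)
  a <- rename_by_position(ann$gene_id, ann)
  b <- rename_by_position(sample(ann$gene_id), ann)
  expect_identical(a, b)
  expect_equal(sort(a$family_name), sort(paste0("TCP", 1:12)))
  expect_equal(anyDuplicated(a$gene_id), 0)
})

test_that("candidates missing from the annotation are reported", {
  ann <- data.frame(gene_id = "a", chrom = "chr1", start = 1, end = 10,
                    strand = "+", stringsAsFactors = FALSE)
  expect_error(rename_by_position(c("a", "ghost"), ann), "ghost")
})
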