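path_network <- function(edges, tfs = character()) {
  ids <- sort(unique(c(edges$gene1, edges$gene2)))
  nodes <- data.frame(gene_id = ids, is_tf = ids %in% tfs,
                      level = NA_integer_, stringsAsFactors = FALSE)
  cogcn:::new_cogcn_network(nodes, edges, pcc_min = 0.9)
}

test_that("pcc matches self, sign-flip and the direct formula", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(pcc(x, x), 1)
  expect_equal(pcc(x, -x), -1)
  set.seed(51)
  for (i in 1:200) {
    a <- stats::rnorm(18); b <- stats::rnorm(18)
    expect_equal(pcc(a, b), oracle_pcc(a, b), tolerance = 1e-12)
  }
  expect_warning(p <- pcc(rep(1, 5), 1:5), "constant")
  expect_true(is.na(p))
  expect_error(pcc(1:2, 1:2), "length")
})

test_that("the PCC edge threshold is inclusive", {
  # two profiles engineered to correlate at exactly their sample PCC
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(1, 2, 3, 4, 5, 7)
  r <- stats::cor(x, y)
  tpm <- rbind(tf = x, g = y)
  colnames(tpm) <- paste0("s", 1:6)
  net <- build_edges(tpm, "tf", pcc_min = r)
  expect_equal(nrow(net$edges), 1)
  net2 <- build_edges(tpm, "tf", pcc_min = r + 1e-12)
  expect_equal(nrow(net2$edges), 0)
})

test_that("noiseless modules yield exactly the within-module TF pairs", {
  sim <- generate_expression(n_genes = 120, n_tf = 10, noise_sd = 0,
                             seed = 6, nontf_per_module = 5)
  filt <- filter_low_expression(sim$tpm)
  net <- build_edges(filt, sim$truth$tf_ids)
  planted <- planted_module_pairs(sim$truth)
  expect_setequal(paste(net$edges$gene1, net$edges$gene2),
                  paste(planted$gene1, planted$gene2))
  expect_true(all(abs(net$edges$weight - 1) < 1e-12))
})

test_that("edge construction is symmetric and monotone in the threshold", {
  sim <- generate_expression(n_genes = 80, n_tf = 8, seed = 7,
                             nontf_per_module = 4)
  filt <- filter_low_expression(sim$tpm)
  lo <- build_edges(filt, sim$truth$tf_ids, pcc_min = 0.85)
  hi <- build_edges(filt, sim$truth$tf_ids, pcc_min = 0.95)
  expect_true(all(paste(hi$edges$gene1, hi$edges$gene2) %in%
                    paste(lo$edges$gene1, lo$edges$gene2)))
  expect_true(all(lo$edges$gene1 < lo$edges$gene2))  # canonical, no duplicates
  expect_equal(anyDuplicated(paste(lo$edges$gene1, lo$edges$gene2)), 0)
})

test_that("tf_vs_all admits TF-TF edges that tf_vs_nontf excludes", {
  sim <- generate_expression(n_genes = 80, n_tf = 8, noise_sd = 0, seed = 8,
                             nontf_per_module = 4)
  filt <- filter_low_expression(sim$tpm)
  narrow <- build_edges(filt, sim$truth$tf_ids)
  wide <- build_edges(filt, sim$truth$tf_ids, pair_scope = "tf_vs_all")
  is_tf_edge <- function(net) {
    net$edges$gene1 %in% sim$truth$tf_ids & net$edges$gene2 %in% sim$truth$tf_ids
  }
  expect_equal(sum(is_tf_edge(narrow)), 0)
  expect_gt(sum(is_tf_edge(wide)), 0)
  expect_error(build_edges(filt, character()), "empty TF set")
})

test_that("bait selection wants a strict T0 peak with tolerant decline", {
  means <- rbind(
    bait = c(10, 8, 6, 4, 2, 1),
    latepeak = c(10, 12, 6, 4, 2, 1),
    flatish = c(10, 9.9, 9.95, 9.9, 9.85, 9.8),
    rebound = c(10, 4, 2, 4, 8, 9))
  colnames(means) <- gradient_treatments()
  expect_equal(select_bait_genes(means), "bait")
  # rel_tol = 0 selects exactly the strictly decreasing T0-peaked profiles
  means2 <- rbind(strict = c(6, 5, 4, 3, 2, 1), tie = c(6, 6, 4, 3, 2, 1),
                  wobble = c(6, 5, 5.01, 3, 2, 1))
  colnames(means2) <- gradient_treatments()
  expect_equal(select_bait_genes(means2, rel_tol = 0), "strict")
})

test_that("the planted bait set is recovered exactly", {
  sim <- generate_expression(seed = 42)
  filt <- filter_low_expression(sim$tpm)
  means <- treatment_means(filt, sim$treatments)
  expect_setequal(select_bait_genes(means), sim$truth$bait_ids)
})

test_that("BFS levels are 1 + shortest-path distance to the nearest bait", {
  edges <- data.frame(gene1 = c("bait", "a"), gene2 = c("a", "b"),
                      weight = 1, stringsAsFactors = FALSE)
  net <- path_network(edges)
  net <- assign_levels_bfs(net, "bait")
  lv <- stats::setNames(net$nodes$level, net$nodes$gene_id)
  expect_equal(unname(lv[c("bait", "a", "b")]), c(1L, 2L, 3L))
})

test_that("isolated nodes stay unassigned and are reported", {
  edges <- data.frame(gene1 = "bait", gene2 = "a", weight = 1,
                      stringsAsFactors = FALSE)
  nodes <- data.frame(gene_id = c("bait", "a", "island"), is_tf = FALSE,
                      level = NA_integer_, stringsAsFactors = FALSE)
  net <- cogcn:::new_cogcn_network(nodes, edges, 0.9)
  expect_message(net <- assign_levels_bfs(net, "bait"), "unreachable")
  expect_true(is.na(net$nodes$level[net$nodes$gene_id == "island"]))
  expect_error(assign_levels_bfs(net, character()), "empty bait")
})

test_that("BFS levels match a Floyd-Warshall oracle on random graphs", {
  set.seed(52)
  for (rep in 1:12) {
    n <- sample(10:120, 1)
    ids <- sprintf("n%03d", seq_len(n))
    m <- sample(1:(3 * n), 1)
    e <- unique(t(apply(matrix(sample(n, 2 * m, replace = TRUE), ncol = 2), 1,
                        sort)))
    e <- e[e[, 1] != e[, 2], , drop = FALSE]
    if (nrow(e) == 0) e <- matrix(c(1L, 2L), ncol = 2)
    edges <- data.frame(gene1 = ids[e[, 1]], gene2 = ids[e[, 2]], weight = 1,
                        stringsAsFactors = FALSE)
    nodes <- data.frame(gene_id = ids, is_tf = FALSE, level = NA_integer_,
                        stringsAsFactors = FALSE)
    net <- cogcn:::new_cogcn_network(nodes, edges, 0.9)
    baits <- sample(ids, sample(1:3, 1))
    got <- suppressMessages(assign_levels_bfs(net, baits))$nodes$level
    D <- floyd_warshall(n, e)
    want <- 1 + apply(D[, match(baits, ids), drop = FALSE], 1, min)
    want[!is.finite(want)] <- NA
    expect_equal(got, as.integer(want))
  }
})

test_that("BFS levels are invariant to edge-list permutation", {
  set.seed(53)
  ids <- sprintf("n%02d", 1:30)
  e <- unique(t(apply(matrix(sample(30, 120, replace = TRUE), ncol = 2), 1, sort)))
  e <- e[e[, 1] != e[, 2], , drop = FALSE]
  edges <- data.frame(gene1 = ids[e[, 1]], gene2 = ids[e[, 2]], weight = 1,
                      stringsAsFactors = FALSE)
  nodes <- data.frame(gene_id = ids, is_tf = FALSE, level = NA_integer_,
                      stringsAsFactors = FALSE)
  a <- suppressMessages(assign_levels_bfs(
    cogcn:::new_cogcn_network(nodes, edges, 0.9), ids[1]))
  b <- suppressMessages(assign_levels_bfs(
    cogcn:::new_cogcn_network(nodes, edges[sample(nrow(edges)), ], 0.9), ids[1]))
  expect_equal(a$nodes$level, b$nodes$level)
})

test_that("hub statistics rank by degree with deterministic ties", {
  leaves <- sprintf("leaf%02d", 1:5)
  edges <- data.frame(gene1 = pmin("hub", leaves), gene2 = pmax("hub", leaves),
                      weight = 0.95, stringsAsFactors = FALSE)
  net <- path_network(edges, tfs = "hub")
  hubs <- hub_statistics(net)
  expect_equal(hubs$gene_id[1], "hub")
  expect_equal(hubs$degree[1], 5L)
  expect_equal(hubs$degree[-1], rep(1L, 5))
  expect_equal(hubs$gene_id[-1], sort(leaves))  # tie-break by id
})

test_that("a planted hub TF tops the degree ranking", {
  sim <- generate_expression(n_genes = 150, n_tf = 5, n_modules = 5,
                             seed = 9, nontf_per_module = 12)
  filt <- filter_low_expression(sim$tpm)
  net <- build_edges(filt, sim$truth$tf_ids)
  hubs <- hub_statistics(net)
  expect_true(hubs$is_tf[1])  # only TFs can touch many non-TF partners
  expect_gte(hubs$degree[1], 12)
})

test_that("network export round-trips through edgelist and graphml", {
  sim <- generate_expression(n_genes = 80, n_tf = 8, seed = 10,
                             nontf_per_module = 4)
  filt <- filter_low_expression(sim$tpm)
  net <- build_edges(filt, sim$truth$tf_ids)
  means <- treatment_means(filt, sim$treatments)
  net <- suppressMessages(assign_levels_bfs(net, select_bait_genes(means)))
  dir <- withr::local_tempdir()
  for (fmt in c("edgelist", "graphml")) {
    path <- file.path(dir, paste0("net.", fmt))
    export_network(net, path, format = fmt)
    back <- import_network(path, format = fmt, pcc_min = net$pcc_min)
    expect_setequal(back$nodes$gene_id, net$nodes$gene_id)
    ord <- match(net$nodes$gene_id, back$nodes$gene_id)
    expect_equal(back$nodes$level[ord], net$nodes$level)
    expect_equal(back$nodes$is_tf[ord], net$nodes$is_tf)
    expect_equal(back$nodes$degree[ord], net$nodes$degree)
    expect_equal(back$edges[order(back$edges$gene1, back$edges$gene2), ],
                 net$edges[order(net$edges$gene1, net$edges$gene2), ],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_error(export_network(net, file.path(dir, "x"), format = "dot"))
})

test_that("SIF export writes one line per edge and a valid empty file", {
  edges <- data.frame(gene1 = c("a", "b"), gene2 = c("b", "c"), weight = 0.95,
                      stringsAsFactors = FALSE)
  net <- path_network(edges)
  dir <- withr::local_tempdir()
  sif <- file.path(dir, "net.sif")
  export_network(net, sif, format = "sif")
  expect_length(readLines(sif), nrow(net$edges))
  back <- import_network(sif, format = "sif")
  expect_setequal(paste(back$edges$gene1, back$edges$gene2),
                  paste(net$edges$gene1, net$edges$gene2))
  # empty network still exports
  empty <- cogcn:::new_cogcn_network(
    data.frame(gene_id = "solo", is_tf = FALSE, level = NA_integer_,
               stringsAsFactors = FALSE),
    edges[0, , drop = FALSE], 0.9)
  export_network(empty, sif, format = "sif")
  expect_length(readLines(sif), 0)
})
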