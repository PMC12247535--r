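# Concentration-ordered co-expression network: Pearson edges between
# TF and non-TF genes at an inclusive threshold, bait-gene selection
# (T0-peaked decreasing profiles), breadth-first-search level
# assignment from the baits, hub statistics and network export.

#' Pearson correlation coefficient between two expression vectors
#'
#' Thin, validated wrapper around the product-moment correlation. A
#' constant vector has no defined correlation; such pairs return `NA`
#' with a warning so callers can skip and log them.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in `[-1, 1]`, or `NA` for a constant vector.
#' @export
pcc <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y) ||
      length(x) < 3 || anyNA(x) || anyNA(y)) {
    stop("`x` and `y` must be finite numeric vectors of equal length >= 3",
         call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("undefined correlation: constant vector", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, y)
}

# internal: construct/validate the network object
new_cogcn_network <- function(nodes, edges, pcc_min) {
  stopifnot(all(c("gene_id", "is_tf") %in% names(nodes)),
            all(c("gene1", "gene2", "weight") %in% names(edges)))
  if (!"level" %in% names(nodes)) nodes$level <- NA_integer_
  deg <- table(factor(c(edges$gene1, edges$gene2), levels = nodes$gene_id))
  nodes$degree <- as.integer(deg[nodes$gene_id])
  structure(list(nodes = nodes, edges = edges, pcc_min = pcc_min),
            class = "cogcn_network")
}

#' @export
print.cogcn_network <- function(x, ...) {
  cat(sprintf("cogcn network: %d nodes (%d TF), %d edges (PCC >= %s), %s levels\n",
              nrow(x$nodes), sum(x$nodes$is_tf), nrow(x$edges),
              format(x$pcc_min),
              if (all(is.na(x$nodes$level))) "no" else "with"))
  invisible(x)
}

#' Build co-expression edges at a PCC threshold
#'
#' Computes Pearson correlations on per-sample TPM values across all
#' samples and keeps every in-scope pair with PCC >= `pcc_min`
#' (inclusive). The default scope pairs TF genes against non-TF genes;
#' `"tf_vs_all"` additionally admits TF-TF edges. Genes with constant
#' profiles have no defined correlation and are skipped with a message.
#'
#' @param tpm numeric matrix, genes x samples (already low-expression
#'   filtered).
#' @param tf_ids character vector of TF gene ids (subset of rownames).
#' @param pcc_min inclusive correlation threshold (default 0.9).
#' @param pair_scope `"tf_vs_nontf"` (default) or `"tf_vs_all"`.
#' @return a `cogcn_network`: list with `nodes` (gene_id, is_tf, level,
#'   degree) and `edges` (gene1, gene2, weight) data.frames.
#' @export
build_edges <- function(tpm, tf_ids, pcc_min = 0.9,
                        pair_scope = c("tf_vs_nontf", "tf_vs_all")) {
  pair_scope <- match.arg(pair_scope)
  check_expression(tpm, stats::setNames(colnames(tpm), colnames(tpm)))
  if (length(tf_ids) == 0) stop("empty TF set", call. = FALSE)
  tf_ids <- unique(tf_ids)
  missing <- setdiff(tf_ids, rownames(tpm))
  if (length(missing) > 0) {
    stop(sprintf("TF id(s) absent from matrix: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  genes <- rownames(tpm)
  constant <- apply(tpm, 1, function(v) stats::sd(v) == 0)
  if (any(constant)) {
    message(sprintf("skipping %d constant-profile gene(s): no defined correlation",
                    sum(constant)))
  }
  usable <- genes[!constant]
  tf_use <- intersect(tf_ids, usable)
  other <- if (pair_scope == "tf_vs_nontf") setdiff(usable, tf_ids) else usable
  edges <- data.frame(gene1 = character(), gene2 = character(),
                      weight = numeric(), stringsAsFactors = FALSE)
  if (length(tf_use) > 0 && length(other) > 0) {
    cors <- stats::cor(t(tpm[tf_use, , drop = FALSE]),
                       t(tpm[other, , drop = FALSE]))
    hit <- which(cors >= pcc_min, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      g1 <- tf_use[hit[, 1]]
      g2 <- other[hit[, 2]]
      keep <- g1 != g2
      g1 <- g1[keep]; g2 <- g2[keep]
      w <- cors[hit][keep]
      lo <- pmin(g1, g2); hi <- pmax(g1, g2)
      key <- paste(lo, hi, sep = "\r")
      dedup <- !duplicated(key)
      edges <- data.frame(gene1 = lo[dedup], gene2 = hi[dedup],
                          weight = w[dedup], stringsAsFactors = FALSE)
      edges <- edges[order(edges$gene1, edges$gene2), , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  nodes <- data.frame(gene_id = genes, is_tf = genes %in% tf_ids,
                      level = NA_integer_, stringsAsFactors = FALSE)
  new_cogcn_network(nodes, edges, pcc_min)
}

#' Select bait genes from treatment means
#'
#' A bait gene peaks at the lowest concentration and declines along the
#' gradient: its T0 mean is the strict maximum of the profile, every
#' successive step either decreases or stays within `tau = rel_tol *
#' (max - min)`, and the final mean lies below the T0 mean by more than
#' `tau`. With `rel_tol = 0` this selects exactly the strictly
#' decreasing T0-peaked profiles.
#'
#' @param means genes x treatments matrix (gradient order, T0 first).
#' @param rel_tol monotonicity tolerance as a fraction of the profile
#'   range (default 0.1).
#' @return character vector of bait gene ids.
#' @export
select_bait_genes <- function(means, rel_tol = 0.1) {
  if (!is.numeric(rel_tol) || rel_tol < 0) {
    stop("`rel_tol` must be non-negative", call. = FALSE)
  }
  is_bait <- apply(means, 1, function(p) {
    rng <- max(p) - min(p)
    if (rng == 0) return(FALSE)
    tau <- rel_tol * rng
    p[1] == max(p) && sum(p == max(p)) == 1 &&
      all(diff(p) <= tau) && p[length(p)] < p[1] - tau
  })
  rownames(means)[is_bait]
}

#' Assign network levels by breadth-first search from the baits
#'
#' All bait nodes get level 1; every other node reachable from a bait
#' gets `1 + d`, where `d` is its unweighted shortest-path distance to
#' the nearest bait. Unreachable nodes keep an unassigned (`NA`) level
#' and are reported with a message.
#'
#' @param network a `cogcn_network`.
#' @param baits character vector of bait gene ids (must be nodes).
#' @return the network with `nodes$level` filled in.
#' @export
assign_levels_bfs <- function(network, baits) {
  stopifnot(inherits(network, "cogcn_network"))
  if (length(baits) == 0) stop("empty bait set", call. = FALSE)
  baits <- unique(baits)
  missing <- setdiff(baits, network$nodes$gene_id)
  if (length(missing) > 0) {
    stop(sprintf("bait(s) absent from network: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  ids <- network$nodes$gene_id
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  adj <- vector("list", n)
  if (nrow(network$edges) > 0) {
    e1 <- idx[network$edges$gene1]
    e2 <- idx[network$edges$gene2]
    for (k in seq_along(e1)) {
      adj[[e1[k]]] <- c(adj[[e1[k]]], e2[k])
      adj[[e2[k]]] <- c(adj[[e2[k]]], e1[k])
    }
  }
  level <- rep(NA_integer_, n)
  queue <- idx[baits]
  level[queue] <- 1L
  head <- 1L
  while (head <= length(queue)) {
    u <- queue[head]; head <- head + 1L
    for (v in adj[[u]]) {
      if (is.na(level[v])) {
        level[v] <- level[u] + 1L
        queue <- c(queue, v)
      }
    }
  }
  if (anyNA(level)) {
    message(sprintf("%d node(s) unreachable from the baits remain unassigned",
                    sum(is.na(level))))
  }
  network$nodes$level <- level
  network
}

#' Hub statistics
#'
#' Node degrees (incident-edge counts) with levels, sorted by degree
#' descending; ties broken deterministically by gene id.
#'
#' @param network a `cogcn_network`.
#' @param focus_ids optional subset of genes to report (default: all).
#' @return data.frame (`gene_id`, `is_tf`, `degree`, `level`).
#' @export
hub_statistics <- function(network, focus_ids = NULL) {
  stopifnot(inherits(network, "cogcn_network"))
  nodes <- network$nodes
  if (!is.null(focus_ids)) nodes <- nodes[nodes$gene_id %in% focus_ids, ,
                                          drop = FALSE]
  nodes <- nodes[order(-nodes$degree, nodes$gene_id), , drop = FALSE]
  rownames(nodes) <- NULL
  nodes[, c("gene_id", "is_tf", "degree", "level")]
}

#' Export a co-expression network
#'
#' Formats: `"edgelist"` (TSV: gene1, gene2, pcc), `"sif"` (one `cx`
#' interaction line per edge) and `"graphml"` (with `is_tf` and `level`
#' node attributes and `weight` edge attributes, via igraph). A
#' node-attribute TSV (`<path>.nodes.tsv`) accompanies the edgelist and
#' SIF formats so the round trip preserves isolated nodes and levels.
#'
#' @param network a `cogcn_network`.
#' @param path output file path.
#' @param format one of `"edgelist"`, `"sif"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("edgelist", "sif", "graphml")) {
  stopifnot(inherits(network, "cogcn_network"))
  format <- match.arg(format)
  nodes <- network$nodes
  edges <- network$edges
  if (format == "graphml") {
    g <- igraph::graph_from_data_frame(
      edges, directed = FALSE,
      vertices = data.frame(name = nodes$gene_id, is_tf = nodes$is_tf,
                            level = as.numeric(nodes$level),
                            stringsAsFactors = FALSE))
    igraph::graph_attr(g, "pcc_min") <- network$pcc_min
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  if (format == "edgelist") {
    utils::write.table(
      data.frame(gene1 = edges$gene1, gene2 = edges$gene2, pcc = edges$weight),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    lines <- if (nrow(edges) > 0) paste(edges$gene1, "cx", edges$gene2) else character()
    writeLines(lines, path)
  }
  utils::write.table(nodes[, c("gene_id", "is_tf", "level", "degree")],
                     paste0(path, ".nodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Import a network written by [export_network()]
#'
#' @param path file path given to [export_network()].
#' @param format the format it was written in.
#' @param pcc_min threshold to record on the rebuilt object (stored in
#'   the file itself for graphml).
#' @return a `cogcn_network`.
#' @export
import_network <- function(path, format = c("edgelist", "sif", "graphml"),
                           pcc_min = NA_real_) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    level <- igraph::vertex_attr(g, "level")
    level[is.nan(level)] <- NA
    nodes <- data.frame(gene_id = igraph::vertex_attr(g, "name"),
                        is_tf = as.logical(igraph::vertex_attr(g, "is_tf")),
                        level = as.integer(level), stringsAsFactors = FALSE)
    el <- igraph::as_data_frame(g, what = "edges")
    edges <- data.frame(gene1 = pmin(el$from, el$to),
                        gene2 = pmax(el$from, el$to),
                        weight = if (nrow(el) > 0) el$weight else numeric(),
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$gene1, edges$gene2), , drop = FALSE]
    rownames(edges) <- NULL
    thr <- igraph::graph_attr(g, "pcc_min")
    return(new_cogcn_network(nodes, edges, if (is.null(thr)) pcc_min else thr))
  }
  nodes <- utils::read.delim(paste0(path, ".nodes.tsv"), stringsAsFactors = FALSE)
  nodes$level <- as.integer(nodes$level)
  if (format == "edgelist") {
    edges <- utils::read.delim(path, stringsAsFactors = FALSE)
    names(edges) <- c("gene1", "gene2", "weight")
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, " ", fixed = TRUE)
    edges <- data.frame(
      gene1 = vapply(parts, `[`, character(1), 1),
      gene2 = vapply(parts, `[`, character(1), 3),
      weight = rep(NA_real_, length(parts)), stringsAsFactors = FALSE)
  }
  new_cogcn_network(nodes[, c("gene_id", "is_tf", "level")], edges, pcc_min)
}
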