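# Gene-family candidate identification: parse homology-search hit
# tables, intersect HMM-profile hits with identity/e-value-filtered
# BLAST hits, and rename the survivors by chromosomal position.

#' Read a BLAST tabular (outfmt 6) hit file
#'
#' Expects the default 12-column layout: qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore.
#'
#' @param path TSV file path.
#' @return data.frame of hits with numeric `pident` and `evalue`.
#' @export
read_blast_outfmt6 <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  lines <- readLines(path)
  keep <- which(!grepl("^#", lines) & nzchar(lines))
  if (length(keep) == 0) {
    return(stats::setNames(
      data.frame(matrix(nrow = 0, ncol = 12), stringsAsFactors = FALSE), cols))
  }
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  n_fields <- lengths(parts)
  if (any(n_fields < 12)) {
    i <- which(n_fields < 12)[1]
    format_error(path, keep[i], sprintf("expected 12 tab-separated fields, found %d",
                                        n_fields[i]))
  }
  m <- do.call(rbind, lapply(parts, `[`, 1:12))
  out <- data.frame(m, stringsAsFactors = FALSE)
  names(out) <- cols
  for (nc in c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
               "sstart", "send", "evalue", "bitscore")) {
    val <- suppressWarnings(as.numeric(out[[nc]]))
    if (anyNA(val)) {
      i <- which(is.na(val))[1]
      format_error(path, keep[i], sprintf("non-numeric value '%s' in column %s",
                                          out[[nc]][i], nc))
    }
    out[[nc]] <- val
  }
  if (any(out$pident < 0 | out$pident > 100)) {
    i <- which(out$pident < 0 | out$pident > 100)[1]
    format_error(path, keep[i], "pident outside [0, 100]")
  }
  if (any(out$evalue < 0)) {
    i <- which(out$evalue < 0)[1]
    format_error(path, keep[i], "negative e-value")
  }
  out
}

#' Read an HMMER per-target tabular file
#'
#' Parses the whitespace-delimited `--tblout`-style layout; lines
#' starting with `#` are comments. Only the first five columns (target
#' name, target accession, query name, query accession, full-sequence
#' e-value) are interpreted.
#'
#' @param path file path.
#' @return data.frame with `target_name`, `query_name`, `evalue`.
#' @export
read_hmmer_tbl <- function(path) {
  lines <- readLines(path)
  keep <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (length(keep) == 0) {
    return(data.frame(target_name = character(), query_name = character(),
                      evalue = numeric(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(trimws(lines[keep]), "[[:space:]]+")
  n_fields <- lengths(parts)
  if (any(n_fields < 5)) {
    i <- which(n_fields < 5)[1]
    format_error(path, keep[i], sprintf("expected >= 5 whitespace-separated fields, found %d",
                                        n_fields[i]))
  }
  evalue <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 5)))
  if (anyNA(evalue)) {
    i <- which(is.na(evalue))[1]
    format_error(path, keep[i], "non-numeric e-value in column 5")
  }
  data.frame(
    target_name = vapply(parts, `[`, character(1), 1),
    query_name = vapply(parts, `[`, character(1), 3),
    evalue = evalue,
    stringsAsFactors = FALSE
  )
}

#' Intersect HMM-profile hits with filtered BLAST hits
#'
#' Family candidates are the gene ids present among the HMM-search hits
#' AND among the BLAST hits that pass the identity and e-value filters.
#' Both boundaries are inclusive (identity >= `identity_min`, e-value <=
#' `evalue_max`). A gene with several BLAST rows survives if any single
#' row passes.
#'
#' @param hmm_hits data.frame from [read_hmmer_tbl()] (or any frame with
#'   the column named by `hmm_id_col`).
#' @param blast_hits data.frame from [read_blast_outfmt6()] (or any
#'   frame with `pident`, `evalue` and the column named by
#'   `blast_id_col`).
#' @param identity_min minimum BLAST percent identity (default 30).
#' @param evalue_max maximum BLAST e-value (default 1e-5).
#' @param blast_id_col column of `blast_hits` holding the candidate gene
#'   id (`"qseqid"` when the family proteome was the query).
#' @param hmm_id_col column of `hmm_hits` holding the candidate gene id.
#' @return sorted character vector of candidate gene ids.
#' @export
intersect_candidates <- function(hmm_hits, blast_hits,
                                 identity_min = 30, evalue_max = 1e-5,
                                 blast_id_col = "qseqid",
                                 hmm_id_col = "target_name") {
  if (!is.numeric(identity_min) || !is.numeric(evalue_max) ||
      identity_min < 0 || evalue_max <= 0) {
    stop("thresholds must be positive numbers", call. = FALSE)
  }
  stopifnot(blast_id_col %in% names(blast_hits), hmm_id_col %in% names(hmm_hits))
  pass <- blast_hits$pident >= identity_min & blast_hits$evalue <= evalue_max
  blast_ids <- unique(blast_hits[[blast_id_col]][pass])
  hmm_ids <- unique(hmm_hits[[hmm_id_col]])
  sort(intersect(hmm_ids, blast_ids))
}

#' Rename family members by chromosomal position
#'
#' Survivor genes are numbered `prefix`1..`prefix`N in order of
#' chromosome (natural sort, so chr2 precedes chr10), then start
#' coordinate, then gene id as the final tie-break. The result does not
#' depend on the input order of `candidates`.
#'
#' @param candidates character vector of gene ids.
#' @param annotation gene annotation: data.frame with `gene_id`,
#'   `chrom`, `start` (as from [read_gene_annotation()]) or a `GRanges`
#'   whose names or `gene_id` metadata column identify genes.
#' @param prefix family name prefix, e.g. `"TCP"`.
#' @return data.frame (`gene_id`, `family_name`, `chrom`, `start`) in
#'   naming order.
#' @export
rename_by_position <- function(candidates, annotation, prefix = "TCP") {
  annotation <- as_gene_annotation(annotation)
  candidates <- unique(candidates)
  missing <- setdiff(candidates, annotation$gene_id)
  if (length(missing) > 0) {
    stop(sprintf("candidate gene(s) missing from annotation: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  ann <- annotation[match(candidates, annotation$gene_id), , drop = FALSE]
  chrom_rank <- match(ann$chrom, unique(ann$chrom)[natural_order(unique(ann$chrom))])
  ord <- order(chrom_rank, ann$start, ann$gene_id)
  out <- data.frame(
    gene_id = ann$gene_id[ord],
    family_name = paste0(prefix, seq_along(ord)),
    chrom = ann$chrom[ord],
    start = ann$start[ord],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
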