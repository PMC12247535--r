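# Promoter extraction and cis-regulatory element (CRE) scanning.
# Promoters are the upstream `upstream` bases of each gene model,
# strand-aware and truncated (never padded) at chromosome ends; CREs are
# IUPAC-encoded motifs scanned on both promoter strands.

#' Read a genome FASTA into a DNAStringSet
#'
#' Sequence names are trimmed to their first whitespace-separated token.
#'
#' @param path FASTA file path.
#' @return `Biostrings::DNAStringSet`.
#' @export
read_genome_fasta <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Read gene models from a GFF3 file
#'
#' Imports the annotation with `rtracklayer` and keeps `gene` features.
#' Coordinates are 1-based closed, as in GFF3.
#'
#' @param path GFF3 file path.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gene_annotation <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) {
      stop(sprintf("format error in '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  gr <- gr[gr$type == "gene"]
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else names(gr)
  if (is.null(ids) || anyNA(ids)) {
    stop(sprintf("format error in '%s': gene features lack ID attributes", path),
         call. = FALSE)
  }
  data.frame(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

# internal: normalize annotation input (data.frame or GRanges)
as_gene_annotation <- function(annotation) {
  if (methods::is(annotation, "GRanges")) {
    ids <- if (!is.null(annotation$gene_id)) as.character(annotation$gene_id)
           else names(annotation)
    if (is.null(ids)) stop("GRanges annotation needs names or a gene_id column",
                           call. = FALSE)
    annotation <- data.frame(
      gene_id = ids,
      chrom = as.character(GenomicRanges::seqnames(annotation)),
      start = GenomicRanges::start(annotation),
      end = GenomicRanges::end(annotation),
      strand = as.character(GenomicRanges::strand(annotation)),
      stringsAsFactors = FALSE
    )
  }
  required <- c("gene_id", "chrom", "start")
  if (!all(required %in% names(annotation))) {
    stop("annotation must provide gene_id, chrom, start (and end, strand for promoter work)",
         call. = FALSE)
  }
  if (anyDuplicated(annotation$gene_id)) {
    stop("annotation contains duplicated gene ids", call. = FALSE)
  }
  annotation
}

#' Extract strand-aware promoter sequences
#'
#' For a `+` gene the promoter is the `upstream` bases immediately 5' of
#' the gene start (`[start - upstream, start - 1]` on the forward
#' strand); for a `-` gene it is `[end + 1, end + upstream]`
#' reverse-complemented. Promoters running off a chromosome end are
#' truncated, never padded, and are returned 5'->3' relative to the
#' gene.
#'
#' @param genome `DNAStringSet` (or FASTA path).
#' @param annotation gene annotation (data.frame or `GRanges`); needs
#'   `end` and `strand` columns.
#' @param upstream promoter length in bp (default 2000).
#' @param gene_ids optional subset of genes to extract (default: all).
#' @return named `DNAStringSet` of promoters (possibly of length 0 for
#'   genes flush against a chromosome end).
#' @export
extract_promoters <- function(genome, annotation, upstream = 2000,
                              gene_ids = NULL) {
  if (is.character(genome) && length(genome) == 1L) genome <- read_genome_fasta(genome)
  stopifnot(methods::is(genome, "DNAStringSet"))
  if (!is.numeric(upstream) || upstream < 1) {
    stop("`upstream` must be a positive length", call. = FALSE)
  }
  ann <- as_gene_annotation(annotation)
  if (!all(c("end", "strand") %in% names(ann))) {
    stop("annotation must provide end and strand for promoter extraction",
         call. = FALSE)
  }
  if (!is.null(gene_ids)) {
    missing <- setdiff(gene_ids, ann$gene_id)
    if (length(missing) > 0) {
      stop(sprintf("gene id(s) absent from annotation: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    ann <- ann[ann$gene_id %in% gene_ids, , drop = FALSE]
  }
  bad_chrom <- setdiff(unique(ann$chrom), names(genome))
  if (length(bad_chrom) > 0) {
    stop(sprintf("chromosome(s) absent from FASTA: %s",
                 paste(bad_chrom, collapse = ", ")), call. = FALSE)
  }
  seqs <- lapply(seq_len(nrow(ann)), function(i) {
    chrom <- genome[[ann$chrom[i]]]
    if (ann$strand[i] == "-") {
      from <- ann$end[i] + 1
      to <- min(length(chrom), ann$end[i] + upstream)
      if (from > to) return(Biostrings::DNAString(""))
      Biostrings::reverseComplement(Biostrings::subseq(chrom, from, to))
    } else {
      from <- max(1, ann$start[i] - upstream)
      to <- ann$start[i] - 1
      if (to < from) return(Biostrings::DNAString(""))
      Biostrings::subseq(chrom, from, to)
    }
  })
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ann$gene_id
  out
}

# internal: validate IUPAC motif patterns
check_iupac <- function(patterns) {
  ok_letters <- names(Biostrings::IUPAC_CODE_MAP)
  for (p in patterns) {
    letters <- strsplit(toupper(p), "")[[1]]
    bad <- setdiff(letters, ok_letters)
    if (length(bad) > 0 || length(letters) == 0) {
      stop(sprintf("invalid IUPAC pattern '%s' (offending symbol: %s)", p,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Read a CRE motif table
#'
#' TSV with columns `element_name`, `iupac_pattern`, `category`.
#'
#' @param path TSV file path.
#' @return validated motif data.frame.
#' @export
read_motif_table <- function(path) {
  motifs <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("element_name", "iupac_pattern", "category")
  if (!all(required %in% names(motifs))) {
    stop(sprintf("format error in '%s': motif table needs columns %s", path,
                 paste(required, collapse = ", ")), call. = FALSE)
  }
  check_iupac(motifs$iupac_pattern)
  motifs
}

#' Scan promoters for IUPAC-encoded cis-regulatory elements
#'
#' Reports every position where a motif matches under IUPAC semantics;
#' overlapping occurrences are all counted. Reverse-strand hits are
#' found by matching the reverse complement of the pattern against the
#' promoter and are reported at the match's leftmost offset on the
#' promoter (forward) strand. Offsets are 0-based.
#'
#' @param promoters named `DNAStringSet`, named character vector, or a
#'   single sequence.
#' @param motifs motif data.frame (`element_name`, `iupac_pattern`,
#'   `category`), e.g. from [read_motif_table()].
#' @param both_strands scan the reverse strand too (default TRUE).
#' @return data.frame with `gene_id`, `element_name`, `category`,
#'   `offset`, `strand`.
#' @export
scan_cres <- function(promoters, motifs, both_strands = TRUE) {
  if (is.character(promoters)) {
    nm <- names(promoters)
    promoters <- Biostrings::DNAStringSet(promoters)
    names(promoters) <- if (is.null(nm)) paste0("seq", seq_along(promoters)) else nm
  }
  if (methods::is(promoters, "DNAString")) {
    promoters <- Biostrings::DNAStringSet(list(promoters))
    names(promoters) <- "seq1"
  }
  stopifnot(methods::is(promoters, "DNAStringSet"))
  check_iupac(motifs$iupac_pattern)
  empty <- data.frame(gene_id = character(), element_name = character(),
                      category = character(), offset = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  rows <- list(empty)
  for (g in seq_along(promoters)) {
    subject <- promoters[[g]]
    if (length(subject) == 0) next
    gene <- names(promoters)[g]
    for (m in seq_len(nrow(motifs))) {
      pat <- Biostrings::DNAString(toupper(motifs$iupac_pattern[m]))
      if (length(pat) > length(subject)) next
      fwd <- Biostrings::matchPattern(pat, subject, fixed = FALSE)
      hits_off <- BiocGenerics::start(fwd) - 1L
      hits_strand <- rep("+", length(hits_off))
      if (isTRUE(both_strands)) {
        rev <- Biostrings::matchPattern(Biostrings::reverseComplement(pat),
                                        subject, fixed = FALSE)
        hits_off <- c(hits_off, BiocGenerics::start(rev) - 1L)
        hits_strand <- c(hits_strand, rep("-", length(BiocGenerics::start(rev))))
      }
      if (length(hits_off) == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = gene,
        element_name = motifs$element_name[m],
        category = motifs$category[m],
        offset = as.integer(hits_off),
        strand = hits_strand,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id, out$offset, out$element_name, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Categorize CRE matches and summarize by functional group
#'
#' Per-gene counts tally motif occurrences in the three functional
#' categories (`stress`, `hormone`, `growth`); elements mapped to any
#' other category are reported in `other_count` and excluded from the
#' three-way total. The family-level summary counts both distinct
#' element types and occurrences per category; percentage shares (one
#' decimal, half-up rounding) are computed on distinct element types,
#' since published element inventories are quoted that way.
#'
#' @param matches data.frame from [scan_cres()].
#' @param category_map optional data.frame (`element_name`, `category`)
#'   overriding the categories carried in `matches`.
#' @return list with `per_gene` (gene_id, stress_count, hormone_count,
#'   growth_count, other_count, total) and `summary` (category,
#'   n_elements, n_occurrences, pct_elements) data.frames.
#' @export
categorize_cres <- function(matches, category_map = NULL) {
  main <- c("stress", "hormone", "growth")
  if (!is.null(category_map)) {
    stopifnot(all(c("element_name", "category") %in% names(category_map)))
    idx <- match(matches$element_name, category_map$element_name)
    matches$category <- ifelse(is.na(idx), "other", category_map$category[idx])
  }
  matches$category[is.na(matches$category) | !(matches$category %in% main)] <- "other"

  genes <- unique(matches$gene_id)
  per_gene <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (cat in c(main, "other")) {
    per_gene[[paste0(cat, "_count")]] <- vapply(genes, function(g) {
      sum(matches$gene_id == g & matches$category == cat)
    }, integer(1), USE.NAMES = FALSE)
  }
  per_gene$total <- per_gene$stress_count + per_gene$hormone_count +
    per_gene$growth_count

  tested <- matches[matches$category %in% main, , drop = FALSE]
  n_elements <- vapply(main, function(cat) {
    length(unique(tested$element_name[tested$category == cat]))
  }, integer(1))
  n_occurrences <- vapply(main, function(cat) sum(tested$category == cat),
                          integer(1))
  pct <- if (sum(n_elements) > 0) count_shares(n_elements, digits = 1)
         else stats::setNames(rep(NA_real_, 3), main)
  summary <- data.frame(
    category = main,
    n_elements = as.integer(n_elements),
    n_occurrences = as.integer(n_occurrences),
    pct_elements = as.numeric(pct),
    stringsAsFactors = FALSE
  )
  rownames(summary) <- NULL
  list(per_gene = per_gene, summary = summary)
}
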