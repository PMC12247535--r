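# Hypergeometric over-representation analysis with Benjamini-Hochberg
# correction, for profiling co-expressed gene sets against a TPM>=1
# background.

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' drawing at least `k` annotated genes in a study set of size `n` from
#' a background of `N` genes of which `K` carry the annotation.
#' Evaluated through the log-space-stable distribution function.
#'
#' @param k observed study hits.
#' @param n study-set size.
#' @param K background genes carrying the term.
#' @param N background size.
#' @return upper-tail probability in `[0, 1]` (vectorized).
#' @export
hypergeom_upper_tail <- function(k, n, K, N) {
  vals <- cbind(k, n, K, N)
  if (any(!is.finite(vals)) || any(vals < 0) ||
      any(vals != floor(vals))) {
    stop("k, n, K, N must be non-negative integers", call. = FALSE)
  }
  k <- unname(vals[, 1]); n <- unname(vals[, 2])
  K <- unname(vals[, 3]); N <- unname(vals[, 4])
  if (any(K > N) || any(n > N) || any(k > pmin(n, K))) {
    stop("need k <= min(n, K), K <= N, n <= N", call. = FALSE)
  }
  unname(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values, clamped to 1, returned in the input
#' order.
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Read a gene-to-term map
#'
#' TSV with columns `gene_id`, `term_id` and optionally `term_name`.
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_term_map <- function(path) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "term_id") %in% names(map))) {
    stop(sprintf("format error in '%s': term map needs gene_id and term_id columns",
                 path), call. = FALSE)
  }
  if (!"term_name" %in% names(map)) map$term_name <- map$term_id
  map
}

#' Over-representation test of a study set
#'
#' One hypergeometric upper-tail test per term with at least one study
#' hit; the BH family is the set of tested terms. Study genes absent
#' from the background are dropped with a warning. Results are sorted
#' by adjusted p, then term id; `significant` flags `adjusted_p <
#' alpha` (strict).
#'
#' @param study character vector of study gene ids.
#' @param background character vector of background gene ids
#'   (superset of `study`).
#' @param term_map data.frame (`gene_id`, `term_id`, optionally
#'   `term_name`).
#' @param alpha significance level on the adjusted p (default 0.05).
#' @return data.frame of `EnrichmentResult` rows: term_id, term_name,
#'   k, n, K, N, p_value, adjusted_p, significant.
#' @export
enrich <- function(study, background, term_map, alpha = 0.05) {
  background <- unique(background)
  study <- unique(study)
  if (length(background) == 0) stop("empty background set", call. = FALSE)
  stray <- setdiff(study, background)
  if (length(stray) > 0) {
    warning(sprintf("%d study gene(s) absent from background were dropped",
                    length(stray)), call. = FALSE)
    study <- intersect(study, background)
  }
  if (!"term_name" %in% names(term_map)) term_map$term_name <- term_map$term_id
  term_map <- term_map[term_map$gene_id %in% background, , drop = FALSE]
  term_map <- term_map[!duplicated(term_map[, c("gene_id", "term_id")]), ,
                       drop = FALSE]
  N <- length(background)
  n <- length(study)
  by_term <- split(term_map$gene_id, term_map$term_id)
  term_names <- term_map$term_name[match(names(by_term), term_map$term_id)]
  k <- vapply(by_term, function(g) length(intersect(g, study)), integer(1))
  K <- lengths(by_term)
  tested <- k >= 1
  out <- data.frame(
    term_id = names(by_term)[tested],
    term_name = term_names[tested],
    k = as.integer(k[tested]),
    n = n,
    K = as.integer(K[tested]),
    N = N,
    stringsAsFactors = FALSE
  )
  if (nrow(out) == 0) {
    out$p_value <- numeric(); out$adjusted_p <- numeric()
    out$significant <- logical()
    return(out)
  }
  out$p_value <- hypergeom_upper_tail(out$k, out$n, out$K, out$N)
  out$adjusted_p <- bh_adjust(out$p_value)
  out$significant <- out$adjusted_p < alpha
  out <- out[order(out$adjusted_p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
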