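# Independent oracles used across the suite: brute-force matchers,
# exhaustive enumerations and closed-form re-computations kept separate
# from the implementation paths they check.

PATTERN_CLASSES <- c("continuous_up", "continuous_down", "biphasic",
                     "reverse_biphasic")

# Kyte-Doolittle hydropathies, retyped from the published scale
ORACLE_KD <- c(
  I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8,
  G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6,
  H = -3.2, E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5
)

random_peptide <- function(max_len = 5, min_len = 1) {
  paste(sample(names(ORACLE_KD), sample(min_len:max_len, 1), replace = TRUE),
        collapse = "")
}

# hand-summed property oracles on short peptides
oracle_gravy <- function(s) {
  aa <- strsplit(s, "")[[1]]
  sum(vapply(aa, function(a) ORACLE_KD[[a]], numeric(1))) / length(aa)
}
oracle_aliphatic <- function(s) {
  aa <- strsplit(s, "")[[1]]
  x <- function(r) 100 * sum(aa == r) / length(aa)
  x("A") + 2.9 * x("V") + 3.9 * (x("I") + x("L"))
}
oracle_instability <- function(s, diwv) {
  aa <- strsplit(s, "")[[1]]
  total <- 0
  for (i in seq_len(length(aa) - 1)) total <- total + diwv[aa[i], aa[i + 1]]
  10 * total / length(aa)
}
oracle_mw <- function(s, masses, water) {
  aa <- strsplit(s, "")[[1]]
  sum(vapply(aa, function(a) masses[[a]], numeric(1))) + water
}

# direct-formula Pearson correlation, term by term
oracle_pcc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  cov_xy <- sum((x - mx) * (y - my)) / (n - 1)
  sd_x <- sqrt(sum((x - mx)^2) / (n - 1))
  sd_y <- sqrt(sum((y - my)^2) / (n - 1))
  cov_xy / (sd_x * sd_y)
}

# exhaustive hypergeometric upper tail by direct enumeration of draw counts
oracle_hyper_upper <- function(k, n, K, N) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Floyd-Warshall all-pairs shortest paths on an unweighted undirected graph
floyd_warshall <- function(n, edges) {
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  if (nrow(edges) > 0) {
    for (i in seq_len(nrow(edges))) {
      D[edges[i, 1], edges[i, 2]] <- 1
      D[edges[i, 2], edges[i, 1]] <- 1
    }
  }
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], "+"))
  D
}

# naive per-position IUPAC matcher (0-based offsets, overlaps included)
ORACLE_IUPAC <- c(A = "A", C = "C", G = "G", T = "T",
                  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
                  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")
oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", s), "")[[1]]),
        collapse = "")
}
naive_iupac_scan <- function(seqstr, pattern, both_strands = TRUE) {
  seq_chars <- strsplit(seqstr, "")[[1]]
  one_strand <- function(pat) {
    pat_chars <- strsplit(pat, "")[[1]]
    L <- length(pat_chars); n <- length(seq_chars)
    if (L > n) return(integer())
    hits <- integer()
    for (o in 0:(n - L)) {
      ok <- TRUE
      for (j in seq_len(L)) {
        if (!grepl(seq_chars[o + j], ORACLE_IUPAC[[pat_chars[j]]], fixed = TRUE)) {
          ok <- FALSE; break
        }
      }
      if (ok) hits <- c(hits, o)
    }
    hits
  }
  fwd_hits <- one_strand(pattern)
  out <- data.frame(offset = fwd_hits, strand = rep("+", length(fwd_hits)),
                    stringsAsFactors = FALSE)
  if (both_strands) {
    rev_hits <- one_strand(oracle_revcomp(pattern))
    out <- rbind(out, data.frame(offset = rev_hits,
                                 strand = rep("-", length(rev_hits)),
                                 stringsAsFactors = FALSE))
  }
  out[order(out$offset, out$strand), , drop = FALSE]
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# sorted match keys for set comparisons
match_key <- function(df) {
  sort(paste(df$gene_id, df$element_name, df$offset, df$strand))
}
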