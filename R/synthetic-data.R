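# Deterministic synthetic-data generators. Every input the pipeline
# consumes can be generated with planted ground truth (module
# membership, bait genes, pattern classes, low-expression genes,
# promoter motif positions, surviving family candidates), so each
# downstream stage has a recoverable answer key and the whole pipeline
# runs offline.

#' Expression archetypes planted in synthetic modules
#'
#' Five treatment-level archetype profiles (linear TPM scale) used for
#' co-expression modules: monotone decreasing (the bait shape),
#' monotone increasing, a peak at T60, a trough at T60 and a peak at
#' T90. Within a module every gene is a positive scaling of the module
#' archetype, so noiseless within-module PCC is exactly 1; the
#' archetypes were chosen so that every positive pairwise linear-scale
#' correlation among them (and against single-spike background
#' profiles) stays below 0.87, under the 0.9 edge threshold even
#' without noise.
#'
#' @return numeric matrix (archetype x 6 treatments) with a
#'   `pattern` attribute giving each archetype's response-pattern
#'   label.
#' @export
synth_archetypes <- function() {
  A <- rbind(
    down = c(100, 55, 30, 17, 9, 5),
    up = c(5, 9, 17, 30, 55, 100),
    peak_early = c(6, 40, 100, 50, 12, 5),
    trough = c(90, 30, 9, 30, 90, 95),
    peak_late = c(5, 12, 50, 100, 40, 6)
  )
  colnames(A) <- gradient_treatments()
  attr(A, "pattern") <- c(
    down = "continuous_down", up = "continuous_up",
    peak_early = "biphasic", trough = "reverse_biphasic",
    peak_late = "biphasic"
  )
  A
}

#' Generate a TPM matrix with planted co-expression structure
#'
#' Builds a nonnegative TPM-like matrix over the six-treatment gradient
#' with `reps` replicates per treatment. Planted structure:
#' * `n_modules` co-expression modules, each with at least one TF and
#'   at least three non-TF genes sharing a scaled archetype profile
#'   ([synth_archetypes()]); noise is multiplicative lognormal
#'   (additive on the log scale), so noiseless within-module PCC is 1
#'   and stays above 0.9 at the default `noise_sd`;
#' * bait genes: every gene of a `down`-archetype module (T0 maximum,
#'   decreasing thereafter);
#' * background genes with a flat baseline plus one elevated off-T0
#'   treatment, so they can never satisfy the bait criterion and carry
#'   no directional pattern (`other`);
#' * low-expression genes with TPM < 1 in every sample.
#'
#' @param n_genes total genes (default 500).
#' @param n_tf number of TF genes, all assigned to modules (default 30).
#' @param n_modules number of modules (default 5).
#' @param reps replicates per treatment (default 3).
#' @param noise_sd lognormal noise sd on the log scale (default 0.1).
#' @param seed RNG seed; the same arguments and seed reproduce the
#'   matrix exactly.
#' @param nontf_per_module non-TF genes per module (default 20).
#' @param low_frac fraction of genes planted as low-expression
#'   (default 0.1).
#' @return list with `tpm` (matrix genes x samples), `treatments`
#'   (named character, sample -> treatment) and `truth` (list:
#'   `module_assignments`, `tf_ids`, `bait_ids`, `pattern_labels`,
#'   `low_expression_ids`, `module_archetype`, `seed`).
#' @export
generate_expression <- function(n_genes = 500, n_tf = 30, n_modules = 5,
                                reps = 3, noise_sd = 0.1, seed = 42,
                                nontf_per_module = 20, low_frac = 0.1) {
  if (any(c(n_genes, n_tf, n_modules, reps) < 1) ||
      any(c(n_genes, n_tf, n_modules, reps) != floor(c(n_genes, n_tf, n_modules, reps)))) {
    stop("counts must be positive integers", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be non-negative", call. = FALSE)
  }
  if (n_tf >= n_genes) stop("need n_tf < n_genes", call. = FALSE)
  if (n_tf < n_modules) stop("need at least one TF per module", call. = FALSE)
  if (nontf_per_module < 3) stop("need >= 3 non-TF genes per module", call. = FALSE)
  n_low <- max(1L, round(low_frac * n_genes))
  n_module_nontf <- n_modules * nontf_per_module
  n_background <- n_genes - n_tf - n_module_nontf - n_low
  if (n_background < 0) {
    stop("n_genes too small for the requested module layout", call. = FALSE)
  }
  set.seed(seed)

  treatments_levels <- gradient_treatments()
  sample_ids <- as.vector(t(outer(treatments_levels, seq_len(reps),
                                  function(tr, r) paste0(tr, "_r", r))))
  treat_of_sample <- stats::setNames(rep(treatments_levels, each = reps),
                                     sample_ids)
  n_samples <- length(sample_ids)
  treat_idx <- rep(seq_along(treatments_levels), each = reps)

  ids <- sample(sprintf("g%05d", seq_len(n_genes)))
  tf_ids <- ids[seq_len(n_tf)]
  nontf_module_ids <- ids[n_tf + seq_len(n_module_nontf)]
  background_ids <- if (n_background > 0) {
    ids[n_tf + n_module_nontf + seq_len(n_background)]
  } else character()
  low_ids <- ids[(n_genes - n_low + 1):n_genes]

  A <- synth_archetypes()
  arch_pattern <- attr(A, "pattern")
  module_arch <- rownames(A)[((seq_len(n_modules) - 1) %% nrow(A)) + 1]
  names(module_arch) <- paste0("M", seq_len(n_modules))

  # even split of TFs over modules, first modules take the remainder
  tf_per_module <- rep(n_tf %/% n_modules, n_modules)
  extra <- n_tf %% n_modules
  if (extra > 0) tf_per_module[seq_len(extra)] <- tf_per_module[seq_len(extra)] + 1L
  module_of <- c(
    rep(names(module_arch), times = tf_per_module),
    rep(names(module_arch), each = nontf_per_module)
  )
  names(module_of) <- c(tf_ids, nontf_module_ids)

  tpm <- matrix(0, nrow = n_genes, ncol = n_samples,
                dimnames = list(ids, sample_ids))
  for (g in c(tf_ids, nontf_module_ids)) {
    arch <- module_arch[[module_of[[g]]]]
    s <- exp(stats::runif(1, log(0.5), log(4)))
    base <- s * A[arch, treat_idx]
    tpm[g, ] <- base * exp(stats::rnorm(n_samples, 0, noise_sd))
  }
  # background genes: flat baseline with one modestly elevated off-T0
  # treatment. The elevation is large against replicate-mean noise (so
  # T0 is never the profile maximum and the bait criterion can never
  # fire) yet small enough that noise attenuation keeps correlations
  # with the peaked archetypes well below the edge threshold.
  for (g in background_ids) {
    level <- exp(stats::runif(1, log(5), log(200)))
    spike_at <- sample(2:6, 1)
    base <- level * ifelse(treat_idx == spike_at, exp(0.35), 1)
    tpm[g, ] <- base * exp(stats::rnorm(n_samples, 0, noise_sd))
  }
  for (g in low_ids) {
    tpm[g, ] <- stats::runif(n_samples, 0.01, 0.9)
  }

  pattern_labels <- c(
    stats::setNames(unname(arch_pattern[module_arch[module_of]]),
                    names(module_of)),
    stats::setNames(rep("other", length(background_ids)), background_ids)
  )
  bait_modules <- names(module_arch)[module_arch == "down"]
  bait_ids <- sort(names(module_of)[module_of %in% bait_modules])

  list(
    tpm = tpm,
    treatments = treat_of_sample,
    truth = list(
      module_assignments = module_of,
      tf_ids = tf_ids,
      bait_ids = bait_ids,
      pattern_labels = pattern_labels,
      low_expression_ids = sort(low_ids),
      module_archetype = module_arch,
      seed = seed
    )
  )
}

#' Planted TF / non-TF co-expression pairs of a synthetic truth
#'
#' Enumerates the within-module TF-to-non-TF gene pairs the edge
#' builder is expected to recover, as a two-column data.frame with
#' `gene1 < gene2`.
#'
#' @param truth the `truth` element of [generate_expression()].
#' @return data.frame (`gene1`, `gene2`).
#' @export
planted_module_pairs <- function(truth) {
  module_of <- truth$module_assignments
  rows <- list()
  for (m in unique(module_of)) {
    members <- names(module_of)[module_of == m]
    tf <- intersect(members, truth$tf_ids)
    nontf <- setdiff(members, truth$tf_ids)
    if (length(tf) == 0 || length(nontf) == 0) next
    grid <- expand.grid(tf = tf, nontf = nontf, stringsAsFactors = FALSE)
    rows[[m]] <- data.frame(gene1 = pmin(grid$tf, grid$nontf),
                            gene2 = pmax(grid$tf, grid$nontf),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$gene1, out$gene2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default synthetic cis-regulatory element catalog
#'
#' Nine IUPAC motifs in the three functional categories used throughout
#' the pipeline. The names follow common plant promoter element
#' nomenclature but the patterns are a synthetic catalog chosen to be
#' mutually non-cross-matching (no realization of one element embeds a
#' match of another on either strand), which the genome generator
#' requires for exact answer keys.
#'
#' @return data.frame (`element_name`, `iupac_pattern`, `category`).
#' @export
default_motif_table <- function() {
  data.frame(
    element_name = c("MBS", "LTR", "TC-rich", "ABRE", "P-box", "CGTCA-motif",
                     "CAT-box", "O2-site", "CCGTCC-box"),
    iupac_pattern = c("CAACTG", "CCGAAA", "ATTTTCTTCA", "TACGTGTC", "CCTTTTG",
                      "CGTCA", "GCCACT", "GATGAYRTGR", "CCGTCC"),
    category = c("stress", "stress", "stress", "hormone", "hormone", "hormone",
                 "growth", "growth", "growth"),
    stringsAsFactors = FALSE
  )
}

# ---- internal IUPAC helpers for the generator (regex route, kept
# independent of the Biostrings-based scanner) ----

IUPAC_OPTIONS <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

iupac_regex <- function(pattern) {
  letters <- strsplit(toupper(pattern), "")[[1]]
  paste0(vapply(letters, function(l) {
    opts <- IUPAC_OPTIONS[[l]]
    if (nchar(opts) == 1) opts else paste0("[", opts, "]")
  }, character(1)), collapse = "")
}

revcomp_string <- function(s) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(s))
  vapply(comp, function(one) {
    paste(rev(strsplit(one, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# all 0-based leftmost offsets (overlaps included) where `pattern`
# matches `seqstr`, on each strand
regex_scan <- function(seqstr, pattern, both_strands = TRUE) {
  find <- function(rx) {
    m <- gregexpr(paste0("(?=", rx, ")"), seqstr, perl = TRUE)[[1]]
    if (m[1] == -1L) integer() else as.integer(m) - 1L
  }
  fwd_off <- find(iupac_regex(pattern))
  out <- data.frame(offset = fwd_off, strand = rep("+", length(fwd_off)),
                    stringsAsFactors = FALSE)
  if (both_strands) {
    rev_off <- find(iupac_regex(revcomp_string(pattern)))
    out <- rbind(out, data.frame(offset = rev_off,
                                 strand = rep("-", length(rev_off)),
                                 stringsAsFactors = FALSE))
  }
  out
}

# realize an IUPAC pattern as a concrete sequence
realize_iupac <- function(pattern) {
  letters <- strsplit(toupper(pattern), "")[[1]]
  paste(vapply(letters, function(l) {
    opts <- strsplit(IUPAC_OPTIONS[[l]], "")[[1]]
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1)), collapse = "")
}

# scan a promoter string for all motifs; returns (element, offset, strand)
scan_all_motifs <- function(seqstr, motifs, both_strands = TRUE) {
  rows <- lapply(seq_len(nrow(motifs)), function(m) {
    hits <- regex_scan(seqstr, motifs$iupac_pattern[m], both_strands)
    if (nrow(hits) == 0) return(NULL)
    data.frame(element_name = motifs$element_name[m], offset = hits$offset,
               strand = hits$strand, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(element_name = character(), offset = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  }
  out
}

#' Generate a toy genome with planted promoter motifs
#'
#' Builds `n_chrom` chromosomes of random sequence carrying
#' `genes_per_chrom` strand-mixed gene models each, with promoter
#' regions (the `upstream` bases 5' of each gene) seeded with concrete
#' realizations of the motif catalog at recorded offsets and strands.
#' The first gene of every chromosome is a `+`-strand gene placed
#' closer than `upstream` to the chromosome start, so its promoter is
#' truncated. Intergenic spacing keeps promoter windows disjoint, and
#' background sequence is re-drawn wherever it would create an
#' unplanted motif match, so a full scan of the promoters returns
#' exactly the recorded occurrences.
#'
#' @param n_chrom chromosomes (default 3).
#' @param genes_per_chrom gene models per chromosome (default 5).
#' @param promoter_motifs motif catalog (default
#'   [default_motif_table()]).
#' @param seed RNG seed.
#' @param upstream promoter length (default 2000).
#' @param gene_length gene-model length in bp (default 600).
#' @return list with `genome` (`DNAStringSet`), `annotation`
#'   (data.frame gene_id, chrom, start, end, strand) and `truth`
#'   (data.frame gene_id, element_name, category, offset, strand —
#'   offsets 0-based within the extracted promoter).
#' @export
generate_genome <- function(n_chrom = 3, genes_per_chrom = 5,
                            promoter_motifs = default_motif_table(),
                            seed = 1, upstream = 2000, gene_length = 600) {
  if (n_chrom < 1 || genes_per_chrom < 1) {
    stop("counts must be positive integers", call. = FALSE)
  }
  check_iupac(promoter_motifs$iupac_pattern)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  max_len <- max(nchar(promoter_motifs$iupac_pattern))

  ann <- list(); chrom_seqs <- list(); truth_rows <- list()
  gene_counter <- 0
  for (ci in seq_len(n_chrom)) {
    chrom <- sprintf("chr%02d", ci)
    # place genes: first gene truncation-testing (+ strand, start < upstream)
    starts <- integer(genes_per_chrom); strands <- character(genes_per_chrom)
    starts[1] <- sample(300:(upstream - 200), 1)
    strands[1] <- "+"
    if (genes_per_chrom > 1) {
      for (gi in 2:genes_per_chrom) {
        gap <- 2 * upstream + sample(100:500, 1)
        starts[gi] <- starts[gi - 1] + gene_length + gap
        strands[gi] <- sample(c("+", "-"), 1)
      }
    }
    ends <- starts + gene_length - 1
    chrom_len <- ends[genes_per_chrom] + upstream + 500
    seq_chars <- sample(bases, chrom_len, replace = TRUE)

    gene_ids <- sprintf("gene%04d", gene_counter + seq_len(genes_per_chrom))
    gene_counter <- gene_counter + genes_per_chrom
    ann[[chrom]] <- data.frame(gene_id = gene_ids, chrom = chrom,
                               start = as.integer(starts),
                               end = as.integer(ends), strand = strands,
                               stringsAsFactors = FALSE)

    for (gi in seq_len(genes_per_chrom)) {
      if (strands[gi] == "+") {
        wstart <- max(1, starts[gi] - upstream); wend <- starts[gi] - 1
      } else {
        wstart <- ends[gi] + 1; wend <- min(chrom_len, ends[gi] + upstream)
      }
      pl <- wend - wstart + 1
      if (pl < max_len) next
      n_plant <- sample(2:4, 1)
      occupied <- matrix(numeric(0), ncol = 2)
      for (k in seq_len(n_plant)) {
        m <- sample(nrow(promoter_motifs), 1)
        pat <- promoter_motifs$iupac_pattern[m]
        len <- nchar(pat)
        planted <- FALSE
        for (attempt in 1:25) {
          o <- sample(0:(pl - len), 1)
          s <- sample(c("+", "-"), 1)
          clash <- nrow(occupied) > 0 &&
            any(o <= occupied[, 2] + 1 & (o + len - 1) >= occupied[, 1] - 1)
          if (clash) next
          r <- realize_iupac(pat)
          q <- if (s == "+") r else revcomp_string(r)
          hits <- scan_all_motifs(q, promoter_motifs)
          if (!(nrow(hits) == 1 && hits$offset == 0 && hits$strand == s &&
                hits$element_name == promoter_motifs$element_name[m])) next
          # promoter offset -> forward-strand coordinates
          fpos <- if (strands[gi] == "+") wstart + o
                  else wend - o - len + 1
          fwd_insert <- if (strands[gi] == "+") q else revcomp_string(q)
          seq_chars[fpos:(fpos + len - 1)] <- strsplit(fwd_insert, "")[[1]]
          occupied <- rbind(occupied, c(o, o + len - 1))
          truth_rows[[length(truth_rows) + 1]] <- data.frame(
            gene_id = gene_ids[gi],
            element_name = promoter_motifs$element_name[m],
            category = promoter_motifs$category[m],
            offset = o, strand = s, stringsAsFactors = FALSE)
          planted <- TRUE
          break
        }
      }
    }
    chrom_seqs[[chrom]] <- seq_chars
  }
  annotation <- do.call(rbind, ann)
  rownames(annotation) <- NULL
  truth <- do.call(rbind, truth_rows)
  truth <- truth[order(truth$gene_id, truth$offset, truth$element_name), ,
                 drop = FALSE]
  rownames(truth) <- NULL

  # scrub incidental matches so the planted set IS the full scan result
  for (iter in 1:60) {
    dirty <- FALSE
    for (gi in seq_len(nrow(annotation))) {
      row <- annotation[gi, ]
      chrom_len <- length(chrom_seqs[[row$chrom]])
      if (row$strand == "+") {
        wstart <- max(1, row$start - upstream); wend <- row$start - 1
      } else {
        wstart <- row$end + 1; wend <- min(chrom_len, row$end + upstream)
      }
      pl <- wend - wstart + 1
      if (pl < 1) next
      fwd <- paste(chrom_seqs[[row$chrom]][wstart:wend], collapse = "")
      promoter <- if (row$strand == "+") fwd else revcomp_string(fwd)
      found <- scan_all_motifs(promoter, promoter_motifs)
      planted_here <- truth[truth$gene_id == row$gene_id, , drop = FALSE]
      key <- function(df) paste(df$element_name, df$offset, df$strand)
      extra <- found[!(key(found) %in% key(planted_here)), , drop = FALSE]
      if (nrow(extra) == 0) next
      dirty <- TRUE
      plen <- nchar(promoter_motifs$iupac_pattern[
        match(extra$element_name, promoter_motifs$element_name)])
      occupied <- planted_here
      occ_len <- nchar(promoter_motifs$iupac_pattern[
        match(occupied$element_name, promoter_motifs$element_name)])
      for (e in seq_len(nrow(extra))) {
        span <- extra$offset[e]:(extra$offset[e] + plen[e] - 1)
        protected <- unlist(lapply(seq_len(nrow(occupied)), function(j) {
          occupied$offset[j]:(occupied$offset[j] + occ_len[j] - 1)
        }))
        redraw <- setdiff(span, protected)
        if (length(redraw) == 0) next
        fwd_pos <- if (row$strand == "+") wstart + redraw
                   else wend - redraw
        chrom_seqs[[row$chrom]][fwd_pos] <- sample(bases, length(fwd_pos),
                                                   replace = TRUE)
      }
    }
    if (!dirty) break
    if (iter == 60) stop("could not scrub incidental motif matches", call. = FALSE)
  }

  genome <- Biostrings::DNAStringSet(vapply(chrom_seqs, paste, character(1),
                                            collapse = ""))
  names(genome) <- names(chrom_seqs)
  list(genome = genome, annotation = annotation, truth = truth)
}

#' Generate BLAST and HMMER hit tables with a known surviving set
#'
#' True family members appear in both tables with BLAST identity >= 30
#' (the first one at exactly 30.0, exercising the inclusive boundary)
#' and e-value <= 1e-5. Decoys are split round-robin over four fates:
#' present only in the BLAST table, present only in the HMM table,
#' present in both but with sub-threshold identity, or present in both
#' with a failing e-value. The intended surviving set of the
#' intersection filter is recorded in the truth.
#'
#' @param true_family_ids gene ids that must survive.
#' @param decoy_ids gene ids that must not survive (disjoint from
#'   `true_family_ids`).
#' @param seed RNG seed.
#' @return list with `blast` (outfmt-6 data.frame), `hmm`
#'   (tblout-style data.frame) and `truth` (list: `survivors`,
#'   `decoy_fate`).
#' @export
generate_hit_tables <- function(true_family_ids, decoy_ids, seed = 1) {
  stopifnot(length(true_family_ids) > 0)
  if (length(intersect(true_family_ids, decoy_ids)) > 0) {
    stop("true and decoy id sets must be disjoint", call. = FALSE)
  }
  set.seed(seed)
  blast_row <- function(id, pident, evalue) {
    len <- sample(120:360, 1)
    data.frame(qseqid = id, sseqid = paste0("RefTCP", sample(1:24, 1)),
               pident = pident, length = len,
               mismatch = sample(0:40, 1), gapopen = sample(0:4, 1),
               qstart = 1, qend = len, sstart = 1, send = len,
               evalue = evalue, bitscore = round(stats::runif(1, 80, 400), 1),
               stringsAsFactors = FALSE)
  }
  hmm_row <- function(id, evalue) {
    data.frame(target_name = id, target_acc = "-", query_name = "TCP",
               query_acc = "PF03634", evalue = evalue,
               score = round(stats::runif(1, 50, 200), 1),
               stringsAsFactors = FALSE)
  }
  blast <- list(); hmm <- list()
  for (i in seq_along(true_family_ids)) {
    id <- true_family_ids[i]
    pident <- if (i == 1) 30.0 else round(stats::runif(1, 30, 95), 1)
    blast[[length(blast) + 1]] <- blast_row(id, pident, 10^-stats::runif(1, 6, 50))
    hmm[[length(hmm) + 1]] <- hmm_row(id, 10^-stats::runif(1, 6, 40))
  }
  fates <- c("blast_only", "hmm_only", "low_identity", "high_evalue")
  decoy_fate <- character(length(decoy_ids))
  for (i in seq_along(decoy_ids)) {
    id <- decoy_ids[i]
    fate <- fates[((i - 1) %% 4) + 1]
    decoy_fate[i] <- fate
    if (fate == "blast_only") {
      blast[[length(blast) + 1]] <- blast_row(id, round(stats::runif(1, 35, 90), 1),
                                              10^-stats::runif(1, 6, 30))
    } else if (fate == "hmm_only") {
      hmm[[length(hmm) + 1]] <- hmm_row(id, 10^-stats::runif(1, 6, 30))
    } else if (fate == "low_identity") {
      blast[[length(blast) + 1]] <- blast_row(id, round(stats::runif(1, 10, 29.9), 1),
                                              10^-stats::runif(1, 6, 30))
      hmm[[length(hmm) + 1]] <- hmm_row(id, 10^-stats::runif(1, 6, 30))
    } else {
      blast[[length(blast) + 1]] <- blast_row(id, round(stats::runif(1, 35, 90), 1),
                                              1e-3)
      hmm[[length(hmm) + 1]] <- hmm_row(id, 10^-stats::runif(1, 6, 30))
    }
  }
  list(
    blast = do.call(rbind, blast),
    hmm = do.call(rbind, hmm),
    truth = list(survivors = sort(true_family_ids),
                 decoy_fate = stats::setNames(decoy_fate, decoy_ids))
  )
}

#' Random protein sequences for synthetic family members
#'
#' Uniform draws over the 20 standard amino acids; used to exercise the
#' property calculators in the demo pipeline.
#'
#' @param ids protein ids.
#' @param min_length,max_length sequence length range.
#' @param seed RNG seed.
#' @return named character vector.
#' @export
random_protein_sequences <- function(ids, min_length = 150, max_length = 400,
                                     seed = 1) {
  set.seed(seed)
  stats::setNames(vapply(ids, function(id) {
    L <- sample(min_length:max_length, 1)
    paste(sample(AA_STANDARD, L, replace = TRUE), collapse = "")
  }, character(1)), ids)
}

#' Synthetic gene-to-term functional map
#'
#' One term per planted module covering exactly that module's genes
#' (so a co-expressed study set is strongly enriched for its module
#' term), plus `n_noise_terms` terms of genes drawn at random from the
#' whole universe.
#'
#' @param truth the `truth` element of [generate_expression()].
#' @param universe all gene ids.
#' @param n_noise_terms number of random terms (default 10).
#' @param seed RNG seed.
#' @return data.frame (`gene_id`, `term_id`, `term_name`).
#' @export
synthetic_term_map <- function(truth, universe, n_noise_terms = 10, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (m in unique(truth$module_assignments)) {
    genes <- names(truth$module_assignments)[truth$module_assignments == m]
    rows[[m]] <- data.frame(gene_id = genes, term_id = paste0("TERM:", m),
                            term_name = paste("module", m, "program"),
                            stringsAsFactors = FALSE)
  }
  for (j in seq_len(n_noise_terms)) {
    genes <- sample(universe, sample(10:40, 1))
    tid <- sprintf("TERM:noise%02d", j)
    rows[[tid]] <- data.frame(gene_id = genes, term_id = tid,
                              term_name = paste("random set", j),
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- file writers (plain-text external interfaces) ----

#' Write expression matrix, sample map and truth to a directory
#'
#' @param sim result of [generate_expression()].
#' @param dir output directory (created if needed).
#' @return named character vector of the files written.
#' @export
write_expression_files <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  matrix_path <- file.path(dir, "expression_tpm.tsv")
  df <- data.frame(gene_id = rownames(sim$tpm), sim$tpm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  map_path <- file.path(dir, "sample_map.tsv")
  utils::write.table(
    data.frame(sample_id = names(sim$treatments),
               treatment = unname(sim$treatments)),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  truth_path <- file.path(dir, "expression_truth.json")
  truth <- sim$truth
  # named atomic vectors must be serialized as objects, not arrays
  for (f in c("module_assignments", "pattern_labels", "module_archetype")) {
    truth[[f]] <- as.list(truth[[f]])
  }
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  c(matrix = matrix_path, sample_map = map_path, truth = truth_path)
}

#' Read back an expression truth JSON
#'
#' Restores the named-vector fields written by
#' [write_expression_files()].
#'
#' @param path path to `expression_truth.json`.
#' @return truth list as produced by [generate_expression()].
#' @export
read_expression_truth <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("module_assignments", "pattern_labels", "module_archetype")) {
    truth[[f]] <- unlist(truth[[f]])
  }
  truth
}

#' Write a synthetic genome as FASTA + GFF3 (+ truth JSON)
#'
#' @param gen result of [generate_genome()].
#' @param dir output directory.
#' @return named character vector of the files written.
#' @export
write_genome_files <- function(gen, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta_path <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(gen$genome, fasta_path, width = 80)
  gff_path <- file.path(dir, "genes.gff3")
  header <- c("##gff-version 3",
              sprintf("##sequence-region %s 1 %d", names(gen$genome),
                      Biostrings::width(gen$genome)))
  body <- sprintf("%s\tcogcn\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                  gen$annotation$chrom, gen$annotation$start,
                  gen$annotation$end, gen$annotation$strand,
                  gen$annotation$gene_id, gen$annotation$gene_id)
  writeLines(c(header, body), gff_path)
  truth_path <- file.path(dir, "genome_truth.json")
  jsonlite::write_json(gen$truth, truth_path, auto_unbox = TRUE, digits = NA)
  c(fasta = fasta_path, gff3 = gff_path, truth = truth_path)
}

#' Write BLAST outfmt-6 and HMMER tabular hit files
#'
#' @param hits result of [generate_hit_tables()].
#' @param dir output directory.
#' @return named character vector of the files written.
#' @export
write_hit_tables <- function(hits, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  blast_path <- file.path(dir, "blast_hits.tsv")
  utils::write.table(hits$blast, blast_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  hmm_path <- file.path(dir, "hmm_hits.tbl")
  lines <- c("# target name  accession  query name  accession  E-value  score",
             "#------------- ---------- ----------- ---------- -------- ------",
             sprintf("%s %s %s %s %.3g %.1f",
                     hits$hmm$target_name, hits$hmm$target_acc,
                     hits$hmm$query_name, hits$hmm$query_acc,
                     hits$hmm$evalue, hits$hmm$score))
  writeLines(lines, hmm_path)
  truth_path <- file.path(dir, "hits_truth.json")
  truth <- hits$truth
  truth$decoy_fate <- as.list(truth$decoy_fate)
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  c(blast = blast_path, hmm = hmm_path, truth = truth_path)
}
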