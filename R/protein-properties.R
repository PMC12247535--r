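# Physicochemical property calculators for protein sequences. These
# reproduce the classical definitions (Kyte-Doolittle GRAVY, Ikai
# aliphatic index, Guruprasad instability index, Bjellqvist-style pI,
# average-mass molecular weight) directly from their residue tables.

# internal: validate and normalize a protein sequence to a character
# vector of single residues. Non-standard letters (including the
# ambiguity codes B, J, O, U, X, Z) are rejected rather than skipped so
# property values are never silently computed on partial sequences.
check_protein <- function(sequence, min_length = 1) {
  if (methods::is(sequence, "AAString") || methods::is(sequence, "AAStringSet")) {
    sequence <- as.character(sequence)
  }
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    stop("`sequence` must be a single protein string", call. = FALSE)
  }
  residues <- strsplit(toupper(sequence), "")[[1]]
  if (length(residues) < min_length) {
    stop(sprintf("sequence must contain at least %d residue(s)", min_length),
         call. = FALSE)
  }
  bad <- setdiff(unique(residues), AA_STANDARD)
  if (length(bad) > 0) {
    stop(sprintf("non-standard residue(s) in sequence: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  residues
}

#' Grand average of hydropathicity (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over all residues. Negative values
#' indicate hydrophilic proteins.
#'
#' @param sequence protein string (standard 20 amino acids only).
#' @return numeric GRAVY score.
#' @examples
#' compute_gravy("AAAA")  # 1.8, the Ala hydropathy
#' @export
compute_gravy <- function(sequence) {
  residues <- check_protein(sequence)
  mean(KD_HYDROPATHY[residues])
}

#' Aliphatic index
#'
#' Ikai's relative volume of aliphatic side chains:
#' `AI = X(Ala) + 2.9 * X(Val) + 3.9 * (X(Ile) + X(Leu))`
#' with `X` the mole percent of each residue.
#'
#' @inheritParams compute_gravy
#' @return numeric aliphatic index (>= 0).
#' @export
compute_aliphatic_index <- function(sequence) {
  residues <- check_protein(sequence)
  molepct <- function(aa) 100 * sum(residues == aa) / length(residues)
  molepct("A") + 2.9 * molepct("V") + 3.9 * (molepct("I") + molepct("L"))
}

#' Instability index
#'
#' Guruprasad dipeptide-weight statistic:
#' `II = (10 / L) * sum(DIWV(x_i, x_{i+1}))` over the L - 1 consecutive
#' dipeptides of a length-L sequence. Values above 40 conventionally
#' predict an in-vitro unstable protein.
#'
#' @inheritParams compute_gravy
#' @return numeric instability index.
#' @export
compute_instability_index <- function(sequence) {
  residues <- check_protein(sequence, min_length = 2)
  L <- length(residues)
  first <- residues[-L]
  second <- residues[-1]
  (10 / L) * sum(DIWV[cbind(first, second)])
}

#' Theoretical isoelectric point
#'
#' Net charge at pH is the Henderson-Hasselbalch sum over the ionizable
#' groups (Asp, Glu, Cys, Tyr side chains and the C-terminus negative;
#' Lys, Arg, His side chains and the N-terminus positive). The pI is the
#' root of the net-charge function, located by bisection on `[0, 14]`.
#'
#' @inheritParams compute_gravy
#' @param pka pKa set from [pka_table()]; the table choice changes the
#'   result and is therefore explicit.
#' @param tol bisection tolerance in pH units.
#' @return numeric pI in (0, 14).
#' @export
compute_pI <- function(sequence, pka = pka_table("bjellqvist"), tol = 1e-3) {
  residues <- check_protein(sequence)
  if (!is.numeric(tol) || tol <= 0) stop("`tol` must be positive", call. = FALSE)
  counts <- table(factor(residues, levels = AA_STANDARD))
  pos_n <- c(Nterm = 1, counts[intersect(names(pka$positive), AA_STANDARD)])
  neg_n <- c(Cterm = 1, counts[intersect(names(pka$negative), AA_STANDARD)])
  charge_at <- function(pH) {
    pos <- sum(pos_n / (1 + 10^(pH - pka$positive[names(pos_n)])))
    neg <- sum(neg_n / (1 + 10^(pka$negative[names(neg_n)] - pH)))
    pos - neg
  }
  lo <- 0; hi <- 14
  if (charge_at(lo) < 0 || charge_at(hi) > 0) {
    stop("net charge does not bracket zero on [0, 14]", call. = FALSE)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (charge_at(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# internal: net charge of a sequence at a pH (exposed for tests via :::)
protein_net_charge <- function(sequence, pH, pka = pka_table("bjellqvist")) {
  residues <- check_protein(sequence)
  counts <- table(factor(residues, levels = AA_STANDARD))
  pos_n <- c(Nterm = 1, counts[intersect(names(pka$positive), AA_STANDARD)])
  neg_n <- c(Cterm = 1, counts[intersect(names(pka$negative), AA_STANDARD)])
  sum(pos_n / (1 + 10^(pH - pka$positive[names(pos_n)]))) -
    sum(neg_n / (1 + 10^(pka$negative[names(neg_n)] - pH)))
}

#' Molecular weight (average mass)
#'
#' Sum of average residue masses plus one water (18.0153 Da).
#'
#' @inheritParams compute_gravy
#' @return numeric mass in Da.
#' @export
compute_molecular_weight <- function(sequence) {
  residues <- check_protein(sequence)
  sum(RESIDUE_MASS_AVG[residues]) + WATER_MASS
}

#' Physicochemical property table for a protein set
#'
#' Computes length, molecular weight, pI, instability index, aliphatic
#' index and GRAVY for each sequence, plus the conventional stability
#' call (`"unstable"` iff instability index > 40).
#'
#' @param sequences named character vector or `Biostrings::AAStringSet`.
#' @param pka pKa set for [compute_pI()].
#' @return data.frame with one row per protein.
#' @export
protein_properties <- function(sequences, pka = pka_table("bjellqvist")) {
  if (methods::is(sequences, "AAStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop("`sequences` must carry unique names", call. = FALSE)
  }
  rows <- lapply(names(sequences), function(id) {
    s <- sequences[[id]]
    ii <- compute_instability_index(s)
    data.frame(
      protein_id = id,
      length = nchar(s),
      molecular_weight = compute_molecular_weight(s),
      pI = compute_pI(s, pka = pka),
      instability_index = ii,
      aliphatic_index = compute_aliphatic_index(s),
      gravy = compute_gravy(s),
      stability = if (ii > 40) "unstable" else "stable",
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
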