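# Expression-matrix handling across the concentration gradient:
# low-expression filtering, replicate means per treatment,
# response-pattern classification and qPCR relative expression.

#' Ordered treatments of the concentration gradient
#'
#' The study design is six NaCl concentrations, T0 (0 mM) through T150
#' (150 mM), each with replicated samples.
#' @return character vector of treatment labels in gradient order.
#' @export
gradient_treatments <- function() c("T0", "T30", "T60", "T90", "T120", "T150")

#' Read an expression matrix and its sample-treatment map
#'
#' The matrix TSV has gene ids in the first column and sample ids as
#' the header; the sidecar map TSV has columns `sample_id`,
#' `treatment`.
#'
#' @param matrix_path expression TSV path.
#' @param sample_map_path sample-map TSV path.
#' @return list with `tpm` (numeric matrix, genes x samples) and
#'   `treatments` (named character vector, sample id -> treatment).
#' @export
read_expression_matrix <- function(matrix_path, sample_map_path) {
  df <- utils::read.delim(matrix_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  tpm <- as.matrix(df[, -1, drop = FALSE])
  rownames(tpm) <- df[[1]]
  storage.mode(tpm) <- "double"
  map <- utils::read.delim(sample_map_path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "treatment") %in% names(map)))
  treatments <- stats::setNames(map$treatment, map$sample_id)
  check_expression(tpm, treatments)
  list(tpm = tpm, treatments = treatments[colnames(tpm)])
}

# internal: validate a TPM matrix + treatment map pair
check_expression <- function(tpm, treatments) {
  if (!is.matrix(tpm) || !is.numeric(tpm)) {
    stop("`tpm` must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  if (any(tpm < 0)) stop("TPM values must be non-negative", call. = FALSE)
  missing <- setdiff(colnames(tpm), names(treatments))
  if (length(missing) > 0) {
    stop(sprintf("sample(s) missing from treatment map: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Filter genes with uniformly low expression
#'
#' A gene is removed iff its TPM is below `tpm_min` in every sample;
#' a single sample at or above the threshold retains the gene. Gene
#' order is preserved. Idempotent.
#'
#' @param tpm numeric matrix, genes x samples.
#' @param tpm_min threshold (default 1).
#' @return filtered matrix.
#' @export
filter_low_expression <- function(tpm, tpm_min = 1) {
  check_expression(tpm, stats::setNames(colnames(tpm), colnames(tpm)))
  keep <- apply(tpm, 1, function(v) any(v >= tpm_min))
  tpm[keep, , drop = FALSE]
}

#' Mean TPM per treatment
#'
#' Arithmetic mean of replicate TPM values per treatment, with
#' treatments returned in gradient order.
#'
#' @param tpm numeric matrix, genes x samples.
#' @param treatments named character vector, sample id -> treatment.
#' @param levels treatment order (default [gradient_treatments()]).
#' @return numeric matrix, genes x treatments.
#' @export
treatment_means <- function(tpm, treatments, levels = gradient_treatments()) {
  check_expression(tpm, treatments)
  treatments <- treatments[colnames(tpm)]
  present <- levels[levels %in% treatments]
  if (length(present) == 0) stop("no samples map to the given treatment levels",
                                 call. = FALSE)
  out <- vapply(present, function(tr) {
    rowMeans(tpm[, treatments == tr, drop = FALSE])
  }, numeric(nrow(tpm)))
  out <- matrix(out, nrow = nrow(tpm),
                dimnames = list(rownames(tpm), present))
  out
}

#' Classify a concentration-response profile
#'
#' Classifies an ordered 6-treatment mean profile into one of four
#' response patterns, with a tolerance band `tau = rel_tol * (max -
#' min)` of the profile:
#' * `continuous_down`: every step non-increasing within `tau` and the
#'   last mean below the first by more than `tau`;
#' * `continuous_up`: the mirror image;
#' * `biphasic`: the profile maximum at an interior treatment,
#'   exceeding both endpoints by more than `tau`;
#' * `reverse_biphasic`: the interior minimum below both endpoints by
#'   more than `tau`;
#' * `other` otherwise (including exactly flat profiles).
#'
#' Monotone classes take precedence over the interior-extremum classes.
#' The rule depends only on the shape of the profile relative to `tau`,
#' so it is invariant to positive rescaling.
#'
#' @param profile numeric vector of 6 ordered treatment means.
#' @param rel_tol tolerance as a fraction of the profile range
#'   (default 0.1).
#' @return character label.
#' @export
classify_pattern <- function(profile, rel_tol = 0.1) {
  if (length(profile) != 6 || !is.numeric(profile) || anyNA(profile)) {
    stop("`profile` must be 6 finite ordered treatment means", call. = FALSE)
  }
  rng <- max(profile) - min(profile)
  if (rng == 0) return("other")
  tau <- rel_tol * rng
  steps <- diff(profile)
  n <- length(profile)
  if (all(steps <= tau) && profile[n] < profile[1] - tau) return("continuous_down")
  if (all(steps >= -tau) && profile[n] > profile[1] + tau) return("continuous_up")
  imax <- which.max(profile)
  if (imax > 1 && imax < n &&
      profile[imax] > profile[1] + tau && profile[imax] > profile[n] + tau) {
    return("biphasic")
  }
  imin <- which.min(profile)
  if (imin > 1 && imin < n &&
      profile[imin] < profile[1] - tau && profile[imin] < profile[n] - tau) {
    return("reverse_biphasic")
  }
  "other"
}

#' Classify all genes of a treatment-mean table
#'
#' @param means genes x treatments matrix from [treatment_means()].
#' @param rel_tol tolerance passed to [classify_pattern()].
#' @return data.frame (`gene_id`, `label`).
#' @export
classify_patterns <- function(means, rel_tol = 0.1) {
  labels <- apply(means, 1, classify_pattern, rel_tol = rel_tol)
  data.frame(gene_id = rownames(means), label = unname(labels),
             stringsAsFactors = FALSE)
}

#' Relative expression by the 2^-ddCt method
#'
#' `2^-((Ct_target,treat - Ct_ref,treat) - (Ct_target,ctrl -
#' Ct_ref,ctrl))`: the fold change of a target gene relative to a
#' reference gene, normalized to the control condition.
#'
#' @param ct_target_treat,ct_ref_treat Ct values under treatment.
#' @param ct_target_ctrl,ct_ref_ctrl Ct values under the control.
#' @return numeric relative expression (vectorized).
#' @export
delta_delta_ct <- function(ct_target_treat, ct_ref_treat,
                           ct_target_ctrl, ct_ref_ctrl) {
  vals <- c(ct_target_treat, ct_ref_treat, ct_target_ctrl, ct_ref_ctrl)
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    stop("Ct values must be finite numbers", call. = FALSE)
  }
  ddct <- (ct_target_treat - ct_ref_treat) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
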