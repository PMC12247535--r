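# Published residue tables used by the physicochemical property
# calculators. All tables are keyed by the 20 standard one-letter codes;
# non-standard letters (B, J, O, U, X, Z) are rejected upstream.

AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Kyte & Doolittle hydropathy scale (J Mol Biol 1982).
KD_HYDROPATHY <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

# Guruprasad dipeptide instability weight values (DIWV; Protein Eng 1990).
# Rows index the first residue of a dipeptide, columns the second.
DIWV <- matrix(c(
  1.0, 44.94, -7.49, 1.0, 1.0, 1.0, -7.49, 1.0, 1.0, 1.0, 1.0, 1.0, 20.26, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0,
  1.0, 1.0, 20.26, 1.0, 1.0, 1.0, 33.6, 1.0, 1.0, 20.26, 33.6, 1.0, 20.26, -6.54, 1.0, 1.0, 33.6, -6.54, 24.68, 1.0,
  1.0, 1.0, 1.0, 1.0, -6.54, 1.0, 1.0, 1.0, -7.49, 1.0, 1.0, 1.0, 1.0, 1.0, -6.54, 20.26, -14.03, 1.0, 1.0, 1.0,
  1.0, 44.94, 20.26, 33.6, 1.0, 1.0, -6.54, 20.26, 1.0, 1.0, 1.0, 1.0, 20.26, 20.26, 1.0, 20.26, 1.0, 1.0, -14.03, 1.0,
  1.0, 1.0, 13.34, 1.0, 1.0, 1.0, 1.0, 1.0, -14.03, 1.0, 1.0, 1.0, 20.26, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 33.601,
  -7.49, 1.0, 1.0, -6.54, 1.0, 13.34, 1.0, -7.49, -7.49, 1.0, 1.0, -7.49, 1.0, 1.0, 1.0, 1.0, -7.49, 1.0, 13.34, -7.49,
  1.0, 1.0, 1.0, 1.0, -9.37, -9.37, 1.0, 44.94, 24.68, 1.0, 1.0, 24.68, -1.88, 1.0, 1.0, 1.0, -6.54, 1.0, -1.88, 44.94,
  1.0, 1.0, 1.0, 44.94, 1.0, 1.0, 13.34, 1.0, -7.49, 20.26, 1.0, 1.0, -1.88, 1.0, 1.0, 1.0, 1.0, -7.49, 1.0, 1.0,
  1.0, 1.0, 1.0, 1.0, 1.0, -7.49, 1.0, -7.49, 1.0, -7.49, 33.6, 1.0, -6.54, 24.64, 33.6, 1.0, 1.0, -7.49, 1.0, 1.0,
  1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, -7.49, 1.0, 1.0, 1.0, 20.26, 33.6, 20.26, 1.0, 1.0, 1.0, 24.68, 1.0,
  13.34, 1.0, 1.0, 1.0, 1.0, 1.0, 58.28, 1.0, 1.0, 1.0, -1.88, 1.0, 44.94, -6.54, -6.54, 44.94, -1.88, 1.0, 1.0, 24.68,
  1.0, -1.88, 1.0, 1.0, -14.03, -14.03, 1.0, 44.94, 24.68, 1.0, 1.0, 1.0, -1.88, -6.54, 1.0, 1.0, -7.49, 1.0, -9.37, 1.0,
  20.26, -6.54, -6.54, 18.38, 20.26, 1.0, 1.0, 1.0, 1.0, 1.0, -6.54, 1.0, 20.26, 20.26, -6.54, 20.26, 1.0, 20.26, -1.88, 1.0,
  1.0, -6.54, 20.26, 20.26, -6.54, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 20.26, 20.26, 1.0, 44.94, 1.0, -6.54, 1.0, -6.54,
  1.0, 1.0, 1.0, 1.0, 1.0, -7.49, 20.26, 1.0, 1.0, 1.0, 1.0, 13.34, 20.26, 20.26, 58.28, 44.94, 1.0, 1.0, 58.28, -6.54,
  1.0, 33.6, 1.0, 20.26, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 44.94, 20.26, 20.26, 20.26, 1.0, 1.0, 1.0, 1.0,
  1.0, 1.0, 1.0, 20.26, 13.34, -7.49, 1.0, 1.0, 1.0, 1.0, 1.0, -14.03, 1.0, -6.54, 1.0, 1.0, 1.0, 1.0, -14.03, 1.0,
  1.0, 1.0, -14.03, 1.0, 1.0, -7.49, 1.0, 1.0, -1.88, 1.0, 1.0, 1.0, 20.26, 1.0, 1.0, 1.0, -7.49, 1.0, 1.0, -6.54,
  -14.03, 1.0, 1.0, 1.0, 1.0, -9.37, 24.68, 1.0, 1.0, 13.34, 24.68, 13.34, 1.0, 1.0, 1.0, 1.0, -14.03, -7.49, 1.0, 1.0,
  24.68, 1.0, 24.68, -6.54, 1.0, -7.49, 13.34, 1.0, 1.0, 1.0, 44.94, 1.0, 13.34, 1.0, -15.91, 1.0, -7.49, 1.0, -9.37, 13.34
), nrow = 20, byrow = TRUE, dimnames = list(AA_STANDARD, AA_STANDARD))

# Average (isotope-abundance-weighted) residue masses in Da; a free
# peptide adds one water.
RESIDUE_MASS_AVG <- c(
  A = 71.0779, C = 103.1429, D = 115.0874, E = 129.1140, F = 147.1738,
  G = 57.0513, H = 137.1393, I = 113.1576, K = 128.1723, L = 113.1576,
  M = 131.1960, N = 114.1026, P = 97.1152, Q = 128.1292, R = 156.1857,
  S = 87.0773, T = 101.1039, V = 99.1310, W = 186.2099, Y = 163.1732
)
WATER_MASS <- 18.0153

#' pKa tables for isoelectric-point calculation
#'
#' Returns a named pKa set for the ionizable groups used by
#' [compute_pI()]. The default `"bjellqvist"` set carries the
#' ProtParam-compatible side-chain and terminal values (positive groups:
#' N-terminus 7.5, Lys 10.0, Arg 12.0, His 5.98; negative groups:
#' C-terminus 3.55, Asp 4.05, Glu 4.45, Cys 9.0, Tyr 10.0). The
#' `"emboss"` set is provided as an alternative. Reported pI values
#' always depend on the table chosen, so the table is explicit and
#' swappable.
#'
#' @param name one of `"bjellqvist"`, `"emboss"`.
#' @return list with numeric vectors `positive` (includes `Nterm`) and
#'   `negative` (includes `Cterm`).
#' @export
pka_table <- function(name = c("bjellqvist", "emboss")) {
  name <- match.arg(name)
  switch(name,
    bjellqvist = list(
      positive = c(Nterm = 7.5, K = 10.0, R = 12.0, H = 5.98),
      negative = c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
    ),
    emboss = list(
      positive = c(Nterm = 8.6, K = 10.8, R = 12.5, H = 6.5),
      negative = c(Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
    )
  )
}
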