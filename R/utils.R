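#' Round half away from zero
#'
#' Standard `round()` rounds halves to even (so 12.5 -> 12); published
#' percentage tables in this field conventionally round halves up
#' (12.5 -> 13). All percentage shares in the package use this rule.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), is.numeric(digits))
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage shares of a count vector
#'
#' Converts a named vector of category counts into percentage shares of
#' their total, rounded half-up to `digits` decimals. Used both for
#' subfamily composition (integer shares) and for cis-element category
#' summaries (one decimal).
#'
#' @param counts named non-negative numeric vector.
#' @param digits decimal places for the shares.
#' @param total optional denominator; defaults to `sum(counts)` but may be
#'   given explicitly when shares are quoted against a larger universe.
#' @return named numeric vector of percentages.
#' @examples
#' count_shares(c(PCF = 13, `CYC/TB1` = 5, CIN = 8))
#' @export
count_shares <- function(counts, digits = 0, total = sum(counts)) {
  if (!is.numeric(counts) || any(counts < 0)) {
    stop("`counts` must be a non-negative numeric vector", call. = FALSE)
  }
  if (total <= 0) stop("total count must be positive", call. = FALSE)
  round_half_up(100 * counts / total, digits)
}

#' Natural (numeric-aware) ordering of strings
#'
#' Orders chromosome-like labels so that "chr2" sorts before "chr10".
#' Runs of digits are compared numerically, everything else
#' lexicographically.
#'
#' @param x character vector.
#' @return integer permutation ordering `x`.
#' @export
natural_order <- function(x) {
  padded <- vapply(x, function(one) {
    hits <- gregexpr("\\d+", one)
    if (hits[[1]][1] == -1L) return(one)
    regmatches(one, hits) <- list(
      formatC(as.numeric(regmatches(one, hits)[[1]]),
              width = 12, flag = "0", format = "d"))
    one
  }, character(1), USE.NAMES = FALSE)
  order(padded, x)
}

# internal: stop with a data-format error carrying a line number
format_error <- function(path, line, msg) {
  stop(sprintf("format error in '%s' line %d: %s", path, line, msg),
       call. = FALSE)
}

# internal: md5 of a file as an unnamed string
file_md5 <- function(path) unname(tools::md5sum(path))
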