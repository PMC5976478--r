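#' Consequence vocabulary
#'
#' The consequence classes recognised for a somatic SNV observation.
#'
#' @return Character vector of the ten recognised consequence tokens.
#' @export
consequence_levels <- function() {
  c("missense", "nonsense", "frameshift", "synonymous", "splice",
    "utr3", "utr5", "intron", "intergenic", "other")
}

#' Silent consequence classes
#'
#' Default set of consequences treated as silent (excluded from non-silent
#' mutation rates and from the background-rate significance test). The set is
#' configurable wherever it is used.
#'
#' @return Character vector.
#' @export
silent_consequences <- function() {
  c("synonymous", "intron", "utr3", "utr5", "intergenic")
}

#' Truncating consequence classes
#' @return Character vector: nonsense and frameshift.
#' @export
truncating_consequences <- function() {
  c("nonsense", "frameshift")
}

DNA_BASES <- c("A", "C", "G", "T")

REPAIR_MECHANISMS <- c("BER", "NER", "MMR", "HRR", "NHEJ", "DDC", "TLS")

#' DNA repair mechanism vocabulary
#'
#' The seven DNA-repair mechanism tokens used by pathway maps and the repair
#' cross-tabulation: base excision repair (BER), nucleotide excision repair
#' (NER), mismatch repair (MMR), homologous recombination repair (HRR),
#' non-homologous end joining (NHEJ), DNA-damage cell-cycle checkpoint
#' signaling (DDC) and translesion synthesis (TLS).
#'
#' @return Character vector of length 7.
#' @export
repair_mechanisms <- function() REPAIR_MECHANISMS

#' Round half away from zero
#'
#' Commercial ("half-up") rounding used when reproducing printed percentages,
#' where `round()`'s round-half-even rule would disagree with the printed
#' value.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Fraction as a printed percentage
#'
#' @param x Fraction in `[0, 1]`.
#' @param digits Decimal digits of the printed percentage (default 1).
#' @return Numeric percentage, rounded half-up.
#' @export
percent <- function(x, digits = 1) round_half_up(100 * x, digits)

# shared reverse-complement lookup (vectorized over single-base vectors)
revcomp_base <- function(b) {
  unname(c(A = "T", C = "G", G = "C", T = "A")[b])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_lum <- function(...) stop(..., call. = FALSE)

assert_prob <- function(p, what = "probabilities") {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop_lum(what, " must lie in [0, 1]")
  }
  invisible(p)
}
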