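#' Round half away from zero
#'
#' Reported percentages use commercial ("half-up") rounding, not the IEC
#' round-half-even rule of [base::round()], so that printed shares such as
#' 92.815 -> 92.82 behave the way bench scientists expect.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  # tiny epsilon guards against representation error (e.g. 1.005 * 100)
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Percentage share with half-up rounding
#'
#' @param count numerator count(s).
#' @param total denominator count.
#' @param digits decimal places (default 2, matching reported precision).
#' @return numeric vector of percentages in \[0, 100\].
#' @export
percent_share <- function(count, total, digits = 2L) {
  stopifnot(is.numeric(count), is.numeric(total), length(total) == 1L)
  if (total <= 0) stop("percent_share: total must be a positive count")
  round_half_up(100 * count / total, digits)
}

# -- small sequence helpers (single strings, transcript-scale) ---------------

dna_to_rna <- function(x) chartr("Tt", "Uu", x)

rna_to_dna <- function(x) chartr("Uu", "Tt", x)

reverse_string <- function(x) {
  vapply(x, function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                              collapse = ""), character(1), USE.NAMES = FALSE)
}

#' Reverse complement of a DNA string
#' @param x character vector of DNA strings (A/C/G/T/N, either case).
#' @return reverse-complemented uppercase DNA strings.
#' @keywords internal
revcomp_dna <- function(x) {
  reverse_string(chartr("ACGTNacgtn", "TGCANTGCAN", x))
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

`%||%` <- function(a, b) if (is.null(a)) b else a
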