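# IUPAC nucleotide codes as 4-bit sets (A=1, C=2, G=4, T=8).
# Primer-side codes match any base in their set; a template N matches nothing
# (encoded 0), mirroring the asymmetry of physical annealing.

IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)

# lookup tables indexed by byte value of the character
.make_lut <- function(codes) {
  lut <- integer(256)
  lut[utf8ToInt(paste(names(codes), collapse = "")) + 1L] <- unname(codes)
  lut[utf8ToInt(paste(tolower(names(codes)), collapse = "")) + 1L] <- unname(codes)
  lut
}
.PRIMER_LUT <- .make_lut(IUPAC_BITS)
# template side: only unambiguous bases carry information; N (and any other
# ambiguity code appearing in an assembly) matches no primer base
.TEMPLATE_LUT <- .make_lut(c(A = 1L, C = 2L, G = 4L, T = 8L))
.TEMPLATE_LUT[utf8ToInt("N") + 1L] <- 0L
.TEMPLATE_LUT[utf8ToInt("n") + 1L] <- 0L

encode_primer <- function(x) {
  codes <- .PRIMER_LUT[utf8ToInt(x) + 1L]
  if (any(codes == 0L)) {
    bad <- unique(strsplit(x, "")[[1]][codes == 0L])
    stop("non-IUPAC character(s) in primer: ", paste(bad, collapse = ", "))
  }
  codes
}

encode_template <- function(x, allow_n = TRUE) {
  ints <- utf8ToInt(x)
  codes <- .TEMPLATE_LUT[ints + 1L]
  known <- .PRIMER_LUT[ints + 1L] != 0L
  if (!all(known)) {
    bad <- unique(intToUtf8(ints[!known], multiple = TRUE))
    stop("non-IUPAC character(s) in template: ", paste(bad, collapse = ", "))
  }
  if (!allow_n && any(codes == 0L))
    stop("ambiguous base in template where A/C/G/T required")
  codes
}

#' Reverse complement of an IUPAC nucleotide string
#'
#' Degeneracy codes are complemented set-wise (e.g. R -> Y, N -> N).
#'
#' @param x single nucleotide string (IUPAC alphabet).
#' @return the reverse-complemented string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Count primer/template mismatches under IUPAC degeneracy
#'
#' A position matches when the template base belongs to the degeneracy set of
#' the primer code at that position. A template `N` never matches (counts as a
#' mismatch), while primer degeneracy codes match every base of their set.
#'
#' @param pattern primer string (IUPAC codes allowed), same length as `window`.
#' @param window template window; `A`/`C`/`G`/`T` plus `N`.
#' @return integer mismatch count.
#' @examples
#' iupac_match_count("AY", "AC") # 0
#' iupac_match_count("AY", "AG") # 1
#' @export
iupac_match_count <- function(pattern, window) {
  stopifnot(is.character(pattern), length(pattern) == 1L,
            is.character(window), length(window) == 1L)
  if (nchar(pattern) != nchar(window))
    stop("pattern and window must have equal length")
  p <- encode_primer(pattern)
  w <- encode_template(window)
  sum(bitwAnd(p, w) == 0L)
}
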