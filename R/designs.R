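#' Primer pair definition
#'
#' Both primers are written 5'->3' as synthesized: the forward primer matches
#' the template top strand directly, the reverse primer is the reverse
#' complement of the top-strand window it addresses.
#'
#' @param name label for the pair.
#' @param forward,reverse IUPAC nucleotide strings, 5'->3'.
#' @param max_mismatch maximum mismatches tolerated per primer.
#' @param terminal_exact number of 3'-terminal bases that must match exactly.
#' @return an object of class `primer_pair`.
#' @export
primer_pair <- function(name, forward, reverse, max_mismatch = 2L,
                        terminal_exact = 3L) {
  stopifnot(nchar(forward) > 0L, nchar(reverse) > 0L,
            max_mismatch >= 0L,
            max_mismatch < nchar(forward), max_mismatch < nchar(reverse),
            terminal_exact >= 0L)
  encode_primer(forward)  # validates alphabet
  encode_primer(reverse)
  structure(
    list(name = name, forward = toupper(forward), reverse = toupper(reverse),
         max_mismatch = as.integer(max_mismatch),
         terminal_exact = as.integer(terminal_exact)),
    class = "primer_pair")
}

#' Amplicon design: primer pair plus length-bound policy
#'
#' @param primers a [primer_pair()].
#' @param min_length,max_length accepted insert length range in bp.
#' @param region_label one of `"V1V3"`, `"V4"`, `"FULL16S"`, `"STRAINID"`, or
#'   a custom label.
#' @return an object of class `amplicon_design`.
#' @export
amplicon_design <- function(primers, min_length, max_length,
                            region_label = "custom") {
  stopifnot(inherits(primers, "primer_pair"),
            min_length > 0, min_length <= max_length)
  structure(
    list(primers = primers, min_length = as.integer(min_length),
         max_length = as.integer(max_length), region_label = region_label),
    class = "amplicon_design")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("<primer_pair> %s\n  forward: %s\n  reverse: %s\n  max_mismatch: %d, terminal_exact: %d\n",
              x$name, x$forward, x$reverse, x$max_mismatch, x$terminal_exact))
  invisible(x)
}

#' @export
print.amplicon_design <- function(x, ...) {
  cat(sprintf("<amplicon_design> %s [%d, %d] bp\n",
              x$region_label, x$min_length, x$max_length))
  print(x$primers)
  invisible(x)
}

# The short-read and full-16S pairs are the standard universal primers
# (27F/534R, 515F/806R, 27F/1492R). The long-design reverse primer targets a
# conserved site in the 23S gene; the commercial kit's sequence is not public,
# so the default is a synthetic stand-in that the shipped operon scaffold
# embeds exactly, and it is overridable via the design config.
STRAINID_23S_REVERSE <- "CCTTAGAGTGCTCTTGCGTA"

#' Default amplicon designs
#'
#' Four designs over the rRNA operon: `V1V3` (27F/534R), `V4` (515F/806R),
#' `FULL16S` (27F/1492R) and the long operon-spanning design `STRAINID`
#' (27F forward with a 23S reverse primer). Every field can be overridden by
#' constructing designs directly or via [read_design_config()].
#'
#' @param max_mismatch,terminal_exact matching policy applied to all pairs.
#' @return named list of [amplicon_design()] objects.
#' @export
default_designs <- function(max_mismatch = 2L, terminal_exact = 3L) {
  pp <- function(name, f, r) primer_pair(name, f, r, max_mismatch, terminal_exact)
  list(
    V1V3 = amplicon_design(
      pp("27F/534R", "AGAGTTTGATCMTGGCTCAG", "ATTACCGCGGCTGCTGG"),
      100L, 600L, "V1V3"),
    V4 = amplicon_design(
      pp("515F/806R", "GTGYCAGCMGCCGCGGTAA", "GGACTACNVGGGTWTCTAAT"),
      100L, 600L, "V4"),
    FULL16S = amplicon_design(
      pp("27F/1492R", "AGAGTTTGATCMTGGCTCAG", "GGTTACCTTGTTACGACTT"),
      1000L, 1800L, "FULL16S"),
    STRAINID = amplicon_design(
      pp("27F/23S-R", "AGAGTTTGATCMTGGCTCAG", STRAINID_23S_REVERSE),
      1000L, 3500L, "STRAINID")
  )
}

#' Read amplicon designs from a YAML config
#'
#' The config is a named map: each entry has `forward`, `reverse` and
#' optionally `max_mismatch`, `terminal_exact`, `min_length`, `max_length`,
#' `region_label`.
#'
#' @param path YAML file path.
#' @return named list of [amplicon_design()] objects.
#' @export
read_design_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- lapply(names(cfg), function(nm) {
    d <- cfg[[nm]]
    amplicon_design(
      primer_pair(nm, d$forward, d$reverse,
                  max_mismatch = d$max_mismatch %||% 2L,
                  terminal_exact = d$terminal_exact %||% 3L),
      min_length = d$min_length %||% 100L,
      max_length = d$max_length %||% 600L,
      region_label = d$region_label %||% nm)
  })
  names(out) <- names(cfg)
  out
}

#' Write amplicon designs to a YAML config
#'
#' @param designs named list of [amplicon_design()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_design_config <- function(designs, path) {
  cfg <- lapply(designs, function(d) list(
    forward = d$primers$forward, reverse = d$primers$reverse,
    max_mismatch = d$primers$max_mismatch,
    terminal_exact = d$primers$terminal_exact,
    min_length = d$min_length, max_length = d$max_length,
    region_label = d$region_label))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
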