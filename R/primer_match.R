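# Vectorized degenerate-primer scanning. Coordinates are 0-based half-open
# internally; report helpers convert to 1-based inclusive.

# mismatch counts of `pcodes` against every window of `tcodes`
.scan_mismatches <- function(tcodes, pcodes) {
  L <- length(tcodes); m <- length(pcodes)
  n_off <- L - m + 1L
  if (n_off < 1L) return(integer(0))
  mm <- integer(n_off)
  for (j in seq_len(m)) {
    mm <- mm + (bitwAnd(tcodes[j:(L - m + j)], pcodes[j]) == 0L)
  }
  mm
}

#' Find degenerate-primer binding sites on both strands
#'
#' Scans a contig for matches of an IUPAC primer within `max_mismatch`
#' mismatches whose `terminal_exact` 3'-terminal bases match exactly. Strand
#' `-` means the primer matches the reverse complement of the top strand; the
#' reported position is always the leftmost top-strand base of the primer
#' footprint (0-based).
#'
#' @param contig nucleotide string (`A`/`C`/`G`/`T`/`N`).
#' @param primer IUPAC primer string, 5'->3'.
#' @param max_mismatch maximum mismatches tolerated.
#' @param terminal_exact number of 3'-terminal primer bases required to match
#'   exactly.
#' @return data.frame with columns `position`, `strand`, `mismatches`, sorted
#'   by (position, strand).
#' @export
find_primer_sites <- function(contig, primer, max_mismatch = 2L,
                              terminal_exact = 3L) {
  stopifnot(is.character(contig), length(contig) == 1L, nchar(contig) > 0L)
  m <- nchar(primer)
  if (max_mismatch >= m) stop("max_mismatch must be smaller than primer length")
  tcodes <- encode_template(contig)
  hits <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") primer else revcomp(primer)
    pcodes <- encode_primer(pat)
    mm <- .scan_mismatches(tcodes, pcodes)
    if (!length(mm)) next
    keep <- mm <= max_mismatch
    if (terminal_exact > 0L && any(keep)) {
      # the primer's 3' end sits at the right end of the footprint on '+',
      # at the left end of the reverse-complemented pattern on '-'
      idx <- if (strand == "+") (m - terminal_exact + 1L):m
             else seq_len(terminal_exact)
      mmt <- integer(length(mm))
      L <- length(tcodes)
      for (j in idx) {
        mmt <- mmt + (bitwAnd(tcodes[j:(L - m + j)], pcodes[j]) == 0L)
      }
      keep <- keep & mmt == 0L
    }
    if (any(keep)) {
      hits[[strand]] <- data.frame(position = which(keep) - 1L,
                                   strand = strand,
                                   mismatches = mm[keep])
    }
  }
  out <- do.call(rbind, unname(hits))
  if (is.null(out))
    out <- data.frame(position = integer(0), strand = character(0),
                      mismatches = integer(0))
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.as_contig_set <- function(genome) {
  if (inherits(genome, "riboamp_genome")) return(genome$contigs)
  if (methods::is(genome, "DNAStringSet")) {
    out <- as.character(genome)
    names(out) <- names(genome)
    return(out)
  }
  stopifnot(is.character(genome))
  if (is.null(names(genome)))
    names(genome) <- paste0("contig", seq_along(genome))
  genome
}

#' In-silico PCR over a set of contigs
#'
#' Pairs each forward-primer site with the nearest compatible downstream
#' reverse-primer site on either strand, forming products whose inter-primer
#' insert is at most `scan_ceiling` bp. Products outside the design's length
#' bounds are still reported, flagged `passed_length_filter = FALSE`, so that
#' over-long products (e.g. across non-contiguous operons) are observed rather
#' than silently lost.
#'
#' @param genome named character vector of contigs, a `DNAStringSet`, or a
#'   genome object from [generate_genome()].
#' @param design an [amplicon_design()].
#' @param scan_ceiling hard upper bound (bp) on the insert length considered
#'   when pairing primer sites.
#' @param genome_label label recorded in the output (defaults to the genome
#'   object's name or `"genome"`).
#' @return data.frame of amplicon hits: `genome`, `contig`, `insert_start`,
#'   `insert_end` (0-based half-open, top strand), `strand`, `length`,
#'   `fwd_mismatches`, `rev_mismatches`, `sequence` (insert only, oriented
#'   5'->3' from the forward primer), `passed_length_filter`.
#' @export
in_silico_pcr <- function(genome, design, scan_ceiling = 10000L,
                          genome_label = NULL) {
  contigs <- .as_contig_set(genome)
  if (is.null(genome_label))
    genome_label <- if (inherits(genome, "riboamp_genome")) genome$name else "genome"
  pr <- design$primers
  mf <- nchar(pr$forward); mr <- nchar(pr$reverse)
  res <- list()
  for (cn in names(contigs)) {
    seqc <- contigs[[cn]]
    fh <- find_primer_sites(seqc, pr$forward, pr$max_mismatch, pr$terminal_exact)
    rh <- find_primer_sites(seqc, pr$reverse, pr$max_mismatch, pr$terminal_exact)
    if (!nrow(fh) || !nrow(rh)) next
    rows <- list()
    # orientation 1: amplicon on the top strand (forward '+', reverse '-')
    fpos <- fh$position[fh$strand == "+"]
    fmm  <- fh$mismatches[fh$strand == "+"]
    rpos <- rh$position[rh$strand == "-"]
    rmm  <- rh$mismatches[rh$strand == "-"]
    if (length(fpos) && length(rpos)) {
      ord <- order(rpos); rpos <- rpos[ord]; rmm <- rmm[ord]
      for (i in seq_along(fpos)) {
        s <- fpos[i] + mf
        j <- which(rpos >= s & rpos - s <= scan_ceiling)
        if (!length(j)) next
        j <- j[1L]
        e <- rpos[j]
        rows[[length(rows) + 1L]] <- data.frame(
          contig = cn, insert_start = s, insert_end = e, strand = "+",
          fwd_mismatches = fmm[i], rev_mismatches = rmm[j],
          sequence = substr(seqc, s + 1L, e))
      }
    }
    # orientation 2: amplicon on the bottom strand (reverse '+', forward '-')
    fpos <- fh$position[fh$strand == "-"]
    fmm  <- fh$mismatches[fh$strand == "-"]
    rpos <- rh$position[rh$strand == "+"]
    rmm  <- rh$mismatches[rh$strand == "+"]
    if (length(fpos) && length(rpos)) {
      ord <- order(rpos, decreasing = TRUE); rpos <- rpos[ord]; rmm <- rmm[ord]
      for (i in seq_along(fpos)) {
        e <- fpos[i]                      # insert ends where fwd footprint begins
        j <- which(rpos + mr <= e & e - (rpos + mr) <= scan_ceiling)
        if (!length(j)) next
        j <- j[1L]
        s <- rpos[j] + mr
        rows[[length(rows) + 1L]] <- data.frame(
          contig = cn, insert_start = s, insert_end = e, strand = "-",
          fwd_mismatches = fmm[i], rev_mismatches = rmm[j],
          sequence = revcomp(substr(seqc, s + 1L, e)))
      }
    }
    if (length(rows)) res[[cn]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, unname(res))
  if (is.null(out)) {
    out <- data.frame(genome = character(0), contig = character(0),
                      insert_start = integer(0), insert_end = integer(0),
                      strand = character(0), length = integer(0),
                      fwd_mismatches = integer(0), rev_mismatches = integer(0),
                      sequence = character(0), passed_length_filter = logical(0))
    return(out)
  }
  out$length <- out$insert_end - out$insert_start
  out$genome <- genome_label
  out$passed_length_filter <- out$length >= design$min_length &
    out$length <= design$max_length
  out <- out[order(out$contig, out$insert_start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("genome", "contig", "insert_start", "insert_end", "strand", "length",
          "fwd_mismatches", "rev_mismatches", "sequence",
          "passed_length_filter")]
}

#' Trim a long amplicon read to a nested sub-region
#'
#' Locates the sub-design's forward and reverse primer sites inside a read
#' (oriented 5'->3' from the parent design's forward primer) and returns the
#' inter-primer insert. Returns `NULL` when either site is absent within the
#' sub-design's mismatch tolerance. With multiple candidate sites the 5'-most
#' forward site and its nearest compatible reverse site are used.
#'
#' When the read is a primer-free insert and the sub-design shares the
#' parent's forward primer (e.g. V1-V3 or full-16S nested in a long operon
#' read, all anchored at 27F), the forward site was removed together with the
#' parent primer; passing `parent_design` anchors such trims at the read's
#' 5' end instead, which is where that primer junction lies.
#'
#' @param read nucleotide string.
#' @param sub_design an [amplicon_design()] whose primers lie inside the read.
#' @param parent_design optional [amplicon_design()] the read came from;
#'   enables the shared-forward-primer anchor described above.
#' @param enforce_length if `TRUE`, also return `NULL` when the trimmed insert
#'   violates the sub-design's length bounds.
#' @return the trimmed insert string, or `NULL` if the read is not convertible.
#' @export
trim_to_subregion <- function(read, sub_design, parent_design = NULL,
                              enforce_length = FALSE) {
  pr <- sub_design$primers
  shared_fwd <- !is.null(parent_design) &&
    identical(pr$forward, parent_design$primers$forward)
  if (shared_fwd) {
    s <- 0L
  } else {
    fh <- find_primer_sites(read, pr$forward, pr$max_mismatch,
                            pr$terminal_exact)
    fh <- fh[fh$strand == "+", , drop = FALSE]
    if (!nrow(fh)) return(NULL)
    s <- fh$position[1L] + nchar(pr$forward)
  }
  rh <- find_primer_sites(read, pr$reverse, pr$max_mismatch, pr$terminal_exact)
  rh <- rh[rh$strand == "-", , drop = FALSE]
  if (!nrow(rh)) return(NULL)
  cand <- rh$position[rh$position >= s]
  if (!length(cand)) return(NULL)
  e <- cand[1L]
  if (enforce_length &&
      (e - s < sub_design$min_length || e - s > sub_design$max_length))
    return(NULL)
  substr(read, s + 1L, e)
}

#' Trim a vector of reads to a sub-region design
#'
#' Vectorized wrapper around [trim_to_subregion()]; non-convertible reads
#' yield `NA`.
#'
#' @inheritParams trim_to_subregion
#' @param reads character vector of reads.
#' @return character vector with `NA` for non-convertible reads.
#' @export
trim_reads <- function(reads, sub_design, parent_design = NULL,
                       enforce_length = FALSE) {
  # reads from clonal amplicons repeat heavily: trim each distinct sequence once
  uq <- unique(reads)
  tr <- vapply(uq, function(r) {
    v <- trim_to_subregion(r, sub_design, parent_design, enforce_length)
    if (is.null(v)) NA_character_ else v
  }, character(1L))
  unname(tr[match(reads, uq)])
}
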