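# rRNA operon census, contiguity screening, and theoretical ASV prediction.

#' Enumerate rRNA operon copies in a genome
#'
#' Annotation-driven when rRNA features are available (preferred), otherwise
#' primer-driven: 16S genes are approximated by the full-16S design's primer
#' sites and the 23S start by the long design's reverse-primer site. Each 16S
#' instance is paired with the nearest same-strand downstream 23S; unpaired
#' copies are reported non-contiguous with an infinite gap.
#'
#' @param genome a [generate_genome()] object or named character vector of
#'   contigs.
#' @param annotations data.frame with columns `contig`, `start`, `end`
#'   (0-based half-open), `strand`, `type` (`rRNA_16S` / `rRNA_23S`; other
#'   types ignored). Defaults to the genome object's truth annotations.
#' @param gap_threshold maximum 16S-end to 23S-start distance (bp) for a copy
#'   to count as contiguous. The default (2000) comfortably covers typical
#'   ITS lengths (< 1500 bp).
#' @param designs default designs used in primer-driven mode.
#' @param mode `"annotation"`, `"primer"`, or `"auto"`.
#' @return data.frame with one row per 16S instance: `genome`, `contig`,
#'   `ssu_start`, `ssu_end`, `lsu_start`, `lsu_end`, `its_start`, `its_end`,
#'   `strand`, `gap_bp` (`Inf` when unpaired), `contiguous`, `copy`.
#' @export
locate_operons <- function(genome, annotations = NULL, gap_threshold = 2000L,
                           designs = default_designs(),
                           mode = c("auto", "annotation", "primer")) {
  mode <- match.arg(mode)
  contigs <- .as_contig_set(genome)
  glabel <- if (inherits(genome, "riboamp_genome")) genome$name else "genome"
  if (is.null(annotations) && inherits(genome, "riboamp_genome"))
    annotations <- genome$annotations
  if (mode == "auto")
    mode <- if (!is.null(annotations)) "annotation" else "primer"

  if (mode == "annotation") {
    if (is.null(annotations)) stop("annotation mode requires annotations")
    if (!all(annotations$contig %in% names(contigs)))
      stop("annotations reference unknown contig(s): ",
           paste(setdiff(annotations$contig, names(contigs)), collapse = ", "))
    ssu <- annotations[annotations$type == "rRNA_16S", , drop = FALSE]
    lsu <- annotations[annotations$type == "rRNA_23S", , drop = FALSE]
  } else {
    ssu <- .primer_ssu(contigs, designs$FULL16S)
    lsu <- .primer_lsu(contigs, designs$STRAINID)
    # the 23S anchor is a primer site inside the gene, not the gene start:
    # allow for the nominal offset of the site into the 23S gene
    gap_threshold <- gap_threshold + 600L
  }
  if (!nrow(ssu)) {
    return(data.frame(genome = character(0), contig = character(0),
                      ssu_start = integer(0), ssu_end = integer(0),
                      lsu_start = integer(0), lsu_end = integer(0),
                      its_start = integer(0), its_end = integer(0),
                      strand = character(0), gap_bp = numeric(0),
                      contiguous = logical(0), copy = integer(0)))
  }
  rows <- lapply(seq_len(nrow(ssu)), function(i) {
    s <- ssu[i, ]
    same <- lsu[lsu$contig == s$contig & lsu$strand == s$strand, , drop = FALSE]
    if (s$strand == "+") {
      cand <- same[same$start >= s$end, , drop = FALSE]
      cand <- cand[order(cand$start), , drop = FALSE]
      gap <- if (nrow(cand)) cand$start[1] - s$end else Inf
    } else {
      cand <- same[same$end <= s$start, , drop = FALSE]
      cand <- cand[order(cand$end, decreasing = TRUE), , drop = FALSE]
      gap <- if (nrow(cand)) s$start - cand$end[1] else Inf
    }
    paired <- nrow(cand) > 0L
    l1 <- if (paired) cand$start[1] else NA_integer_
    l2 <- if (paired) cand$end[1] else NA_integer_
    its <- if (!paired) c(NA_integer_, NA_integer_)
           else if (s$strand == "+") c(s$end, l1) else c(l2, s$start)
    data.frame(genome = glabel, contig = s$contig,
               ssu_start = s$start, ssu_end = s$end,
               lsu_start = l1, lsu_end = l2,
               its_start = its[1], its_end = its[2],
               strand = s$strand, gap_bp = gap,
               contiguous = paired && is.finite(gap) && gap <= gap_threshold)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$contig, out$ssu_start), , drop = FALSE]
  out$copy <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# approximate 16S intervals from full-16S primer sites (footprints included)
.primer_ssu <- function(contigs, design) {
  hits <- in_silico_pcr(contigs, design, genome_label = "g")
  if (!nrow(hits)) {
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  }
  mf <- nchar(design$primers$forward); mr <- nchar(design$primers$reverse)
  data.frame(contig = hits$contig,
             start = ifelse(hits$strand == "+", hits$insert_start - mf,
                            hits$insert_start - mr),
             end = ifelse(hits$strand == "+", hits$insert_end + mr,
                          hits$insert_end + mf),
             strand = hits$strand)
}

# approximate 23S anchors from the long design's reverse-primer sites
.primer_lsu <- function(contigs, design) {
  pr <- design$primers
  res <- lapply(names(contigs), function(cn) {
    h <- find_primer_sites(contigs[[cn]], pr$reverse, pr$max_mismatch,
                           pr$terminal_exact)
    if (!nrow(h)) return(NULL)
    m <- nchar(pr$reverse)
    # a '-' site belongs to a top-strand ('+') operon and vice versa
    data.frame(contig = cn, start = h$position, end = h$position + m,
               strand = ifelse(h$strand == "-", "+", "-"))
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0))
  out
}

# assign each census copy its amplicon hits under a design
.copy_status <- function(genome, design, census, scan_ceiling = 10000L) {
  hits <- in_silico_pcr(genome, design, scan_ceiling = scan_ceiling)
  status <- rep(NA_character_, nrow(census))
  seqs <- rep(NA_character_, nrow(census))
  if (nrow(hits)) {
    span_lo <- pmin(census$ssu_start,
                    ifelse(is.na(census$lsu_start), census$ssu_start,
                           census$lsu_start))
    span_hi <- pmax(census$ssu_end,
                    ifelse(is.na(census$lsu_end), census$ssu_end,
                           census$lsu_end))
    for (k in seq_len(nrow(hits))) {
      ov <- which(census$contig == hits$contig[k] &
                    span_lo < hits$insert_end[k] &
                    span_hi > hits$insert_start[k])
      for (ci in ov) {
        if (hits$passed_length_filter[k]) {
          status[ci] <- "amplifiable"
          seqs[ci] <- hits$sequence[k]
        } else if (is.na(status[ci]) || status[ci] != "amplifiable") {
          status[ci] <- "length"
        }
      }
    }
  }
  miss <- is.na(status)
  status[miss & !census$contiguous] <- "non_contiguous"
  status[is.na(status)] <- "mismatch"
  list(status = status, sequence = seqs)
}

#' Theoretical ASV counts per taxon and design
#'
#' Extracts the design's insert from every amplifiable operon copy and counts
#' distinct sequences: the number of amplicon sequence variants an error-free
#' workflow would recover for that taxon.
#'
#' @param genomes list of genome objects (or a single genome).
#' @param design an [amplicon_design()].
#' @param gap_threshold passed to [locate_operons()].
#' @return data.frame per taxon: `taxon`, `design`, `operon_copies`,
#'   `amplifiable_copies`, `unique_amplicons`, and `amplicon_sequences`
#'   (list column of the distinct insert sequences).
#' @export
theoretical_asv_count <- function(genomes, design, gap_threshold = 2000L) {
  if (inherits(genomes, "riboamp_genome")) genomes <- list(genomes)
  rows <- lapply(genomes, function(g) {
    census <- locate_operons(g, gap_threshold = gap_threshold)
    st <- .copy_status(g, design, census)
    seqs <- unique(st$sequence[st$status == "amplifiable"])
    if (!length(seqs))
      warning("taxon ", g$name, " has no amplifiable operon copy under ",
              design$region_label)
    data.frame(taxon = g$name, design = design$region_label,
               operon_copies = nrow(census),
               amplifiable_copies = sum(st$status == "amplifiable"),
               unique_amplicons = length(seqs),
               amplicon_sequences = I(list(seqs)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-copy design compatibility report
#'
#' Assigns every operon copy of every genome exactly one status under each
#' design: `amplifiable`, or excluded as `length` (product outside bounds),
#' `non_contiguous` (no paired 23S within the gap threshold and no product),
#' or `mismatch` (contiguous but a primer fails to bind).
#'
#' @param genomes list of genome objects (or one genome).
#' @param designs named list of [amplicon_design()] objects.
#' @param gap_threshold passed to [locate_operons()].
#' @return data.frame: `taxon`, `design`, `copy`, `status`.
#' @export
design_compatibility_report <- function(genomes, designs = default_designs(),
                                        gap_threshold = 2000L) {
  if (inherits(genomes, "riboamp_genome")) genomes <- list(genomes)
  rows <- list()
  for (g in genomes) {
    census <- locate_operons(g, gap_threshold = gap_threshold)
    for (dn in names(designs)) {
      st <- .copy_status(g, designs[[dn]], census)
      rows[[length(rows) + 1L]] <- data.frame(
        taxon = g$name, design = designs[[dn]]$region_label,
        copy = census$copy, status = st$status)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
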