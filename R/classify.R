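# LCA taxonomic classification against a labeled reference amplicon set.

TAXONOMIC_RANKS <- c("domain", "phylum", "class", "order", "family",
                     "genus", "species", "strain")

.rank_depth <- function(rank) {
  d <- match(rank, TAXONOMIC_RANKS)
  if (is.na(d)) stop("unknown rank: ", rank)
  d
}

# Hamming distance for equal-length strings (byte-wise)
.hamming <- function(a, b) sum(charToRaw(a) != charToRaw(b))

# substitution-oriented distance: Hamming on equal lengths, edit distance for
# small length differences, Inf otherwise
.seq_distance <- function(query, refs, max_len_diff = 10L) {
  ql <- nchar(query)
  rl <- nchar(refs)
  d <- rep(Inf, length(refs))
  eq <- rl == ql
  if (any(eq)) d[eq] <- vapply(refs[eq], .hamming, numeric(1L), a = query)
  near <- !eq & abs(rl - ql) <= max_len_diff
  if (any(near))
    d[near] <- as.numeric(utils::adist(query, refs[near]))
  d
}

#' Build a reference amplicon set
#'
#' Validates reference entries: every lineage must be a semicolon-separated
#' prefix-consistent list of at most eight rank labels
#' (domain;phylum;class;order;family;genus;species;strain).
#'
#' @param ids,sequences,lineages parallel character vectors.
#' @return data.frame of class `amplicon_reference`.
#' @export
amplicon_reference <- function(ids, sequences, lineages) {
  stopifnot(length(ids) == length(sequences),
            length(ids) == length(lineages), !anyDuplicated(ids))
  parts <- strsplit(lineages, ";", fixed = TRUE)
  ok <- vapply(parts, function(p) {
    length(p) >= 1L && length(p) <= length(TAXONOMIC_RANKS) &&
      all(nzchar(trimws(p)))
  }, logical(1L))
  if (!all(ok))
    stop("malformed lineage(s): ",
         paste(lineages[!ok], collapse = " | "))
  structure(data.frame(id = ids, sequence = toupper(sequences),
                       lineage = lineages, stringsAsFactors = FALSE),
            class = c("amplicon_reference", "data.frame"))
}

#' Reference set from a collection of genomes
#'
#' Uses the theoretical amplicon sequences of each genome under a design as
#' reference entries carrying the genome's full lineage, emulating a curated
#' full-operon reference database on synthetic truth.
#'
#' @param genomes list of [generate_genome()] objects.
#' @param design an [amplicon_design()].
#' @return an [amplicon_reference()].
#' @export
reference_from_genomes <- function(genomes, design) {
  rows <- list()
  for (g in genomes) {
    rec <- theoretical_asv_count(list(g), design)
    seqs <- rec$amplicon_sequences[[1]]
    if (!length(seqs)) next
    lin <- paste(g$lineage, collapse = ";")
    for (i in seq_along(seqs)) {
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("%s_amp%d", g$name, i), sequence = seqs[i],
        lineage = lin)
    }
  }
  df <- do.call(rbind, rows)
  amplicon_reference(df$id, df$sequence, df$lineage)
}

#' Classify features by lowest common ancestor of best reference matches
#'
#' For each feature, finds all reference amplicons at the minimum distance
#' (substitution-only Hamming on equal lengths, edit distance for length
#' differences of at most 10 bp) provided it does not exceed `max_distance`;
#' the assignment is the longest common lineage prefix of those matches.
#' Features with no acceptable match are `"unclassified"`.
#'
#' @param x a [feature_table()] or named character vector of sequences.
#' @param reference an [amplicon_reference()].
#' @param max_distance maximum acceptable distance; default 1% of the
#'   feature's length.
#' @return data.frame: `feature_id`, `lineage` (semicolon-separated, `""` if
#'   unclassified), `deepest_rank`.
#' @export
classify_lca <- function(x, reference, max_distance = NULL) {
  seqs <- if (inherits(x, "feature_table")) x$sequences else x
  stopifnot(!is.null(seqs), !is.null(names(seqs)))
  ref_lin <- strsplit(reference$lineage, ";", fixed = TRUE)
  res <- lapply(names(seqs), function(fid) {
    q <- seqs[[fid]]
    lim <- if (is.null(max_distance)) ceiling(0.01 * nchar(q)) else max_distance
    d <- .seq_distance(q, reference$sequence)
    best <- min(d)
    if (!is.finite(best) || best > lim) {
      return(data.frame(feature_id = fid, lineage = "",
                        deepest_rank = "unclassified"))
    }
    hits <- ref_lin[d == best]
    lca <- hits[[1]]
    for (h in hits[-1]) {
      k <- min(length(lca), length(h))
      same <- which(lca[seq_len(k)] != h[seq_len(k)])
      keep <- if (length(same)) same[1] - 1L else k
      lca <- lca[seq_len(keep)]
      if (!length(lca)) break
    }
    if (!length(lca)) {
      data.frame(feature_id = fid, lineage = "",
                 deepest_rank = "unclassified")
    } else {
      data.frame(feature_id = fid, lineage = paste(lca, collapse = ";"),
                 deepest_rank = TAXONOMIC_RANKS[length(lca)])
    }
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# label of each feature at `rank`, NA when not classified that deep
taxon_at_rank <- function(assignments, rank) {
  depth <- .rank_depth(rank)
  parts <- strsplit(assignments$lineage, ";", fixed = TRUE)
  lab <- vapply(parts, function(p) {
    if (length(p) >= depth) p[[depth]] else NA_character_
  }, character(1L))
  stats::setNames(lab, assignments$feature_id)
}

#' Per-sample proportion of reads classified at a rank or deeper
#'
#' @param table a [feature_table()].
#' @param assignments data.frame from [classify_lca()].
#' @param rank target rank.
#' @return list with `per_sample` (named proportions) and `median`.
#' @export
classification_rate <- function(table, assignments, rank = "genus") {
  stopifnot(inherits(table, "feature_table"))
  ids <- rownames(table$counts)
  if (!all(ids %in% assignments$feature_id))
    stop("every feature needs an assignment")
  depth <- .rank_depth(rank)
  adepth <- ifelse(assignments$deepest_rank == "unclassified", 0L,
                   match(assignments$deepest_rank, TAXONOMIC_RANKS))
  ok <- assignments$feature_id[adepth >= depth]
  num <- colSums(table$counts[ids %in% ok, , drop = FALSE])
  den <- colSums(table$counts)
  rates <- num / den
  list(per_sample = rates, median = stats::median(rates))
}
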