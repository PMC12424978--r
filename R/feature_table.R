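# Feature tables: exact-dereplication ASV calling, rarefaction, aggregation.

#' Construct a feature table
#'
#' A features x samples matrix of non-negative integer counts, with the
#' feature sequences attached. All-zero feature rows are dropped.
#'
#' @param counts integer matrix, features in rows, samples in columns, both
#'   dimnames set.
#' @param sequences named character vector mapping feature ids to sequences;
#'   may be `NULL` for tables whose rows are taxa rather than sequences
#'   (e.g. after [aggregate_taxa()]).
#' @return object of class `feature_table`.
#' @export
feature_table <- function(counts, sequences = NULL) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)), all(counts >= 0),
            all(counts == round(counts)))
  storage.mode(counts) <- "integer"
  keep <- rowSums(counts) > 0L
  counts <- counts[keep, , drop = FALSE]
  if (!is.null(sequences)) {
    if (!all(rownames(counts) %in% names(sequences)))
      stop("every feature id must have a sequence")
    sequences <- sequences[rownames(counts)]
  }
  structure(list(counts = counts, sequences = sequences),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d features x %d samples, %d reads\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$counts)

#' Dereplicate reads into exact amplicon sequence variants
#'
#' Features are the distinct read sequences; counts are per-sample occurrence
#' counts. This exact dereplication replaces model-based denoising and is
#' lossless on error-free reads. Features whose total count across samples is
#' below `min_total_count` are removed.
#'
#' @param reads named list: sample id -> character vector of primer-free
#'   insert sequences in consistent orientation. Reads that are `NA` (e.g.
#'   non-convertible trims) are ignored.
#' @param min_total_count minimum total count for a feature to be retained.
#' @return a [feature_table()] with features named `ASV1`, `ASV2`, ... in
#'   decreasing total-count order (ties broken by sequence).
#' @export
dereplicate_asvs <- function(reads, min_total_count = 1L) {
  stopifnot(is.list(reads), !is.null(names(reads)))
  reads <- lapply(reads, function(r) r[!is.na(r)])
  uniq <- unique(unlist(reads, use.names = FALSE))
  if (!length(uniq)) {
    m <- matrix(integer(0), 0, length(reads),
                dimnames = list(character(0), names(reads)))
    return(structure(list(counts = m,
                          sequences = stats::setNames(character(0),
                                                      character(0))),
                     class = "feature_table"))
  }
  m <- vapply(reads, function(r) tabulate(match(r, uniq), length(uniq)),
              integer(length(uniq)))
  m <- matrix(m, nrow = length(uniq),
              dimnames = list(NULL, names(reads)))
  tot <- rowSums(m)
  keep <- tot >= min_total_count
  m <- m[keep, , drop = FALSE]; uniq <- uniq[keep]; tot <- tot[keep]
  ord <- order(-tot, uniq)
  m <- m[ord, , drop = FALSE]; uniq <- uniq[ord]
  ids <- sprintf("ASV%d", seq_along(uniq))
  rownames(m) <- ids
  feature_table(m, stats::setNames(uniq, ids))
}

#' Rarefy a feature table to an even depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric) to exactly `depth`; samples with fewer reads than `depth`
#' are dropped with a warning.
#'
#' @param table a [feature_table()].
#' @param depth target reads per sample (> 0).
#' @param seed RNG seed; rarefaction is deterministic given the seed.
#' @return a rarefied [feature_table()].
#' @export
rarefy <- function(table, depth, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  if (depth <= 0) stop("depth must be positive")
  m <- table$counts
  totals <- colSums(m)
  low <- totals < depth
  if (any(low))
    warning("dropping sample(s) below depth ", depth, ": ",
            paste(colnames(m)[low], collapse = ", "))
  m <- m[, !low, drop = FALSE]
  with_seed(seed, {
    out <- apply(m, 2L, function(cnt) {
      pool <- rep.int(seq_along(cnt), cnt)
      tabulate(sample(pool, depth), nbins = length(cnt))
    })
    out <- matrix(out, nrow = nrow(m), dimnames = dimnames(m))
    feature_table(out, table$sequences)
  })
}

#' Aggregate a feature table at a taxonomic rank
#'
#' Sums counts over features sharing the same label at `rank`; features not
#' classified at that depth are pooled into `"unclassified"`.
#'
#' @param table a [feature_table()].
#' @param assignments a data.frame from [classify_lca()].
#' @param rank one of the eight ranks (`"domain"` ... `"strain"`).
#' @return a [feature_table()] keyed by taxon label (no sequences).
#' @export
aggregate_taxa <- function(table, assignments, rank = "genus") {
  stopifnot(inherits(table, "feature_table"))
  lab <- taxon_at_rank(assignments, rank)
  lab <- lab[rownames(table$counts)]
  lab[is.na(lab)] <- "unclassified"
  agg <- rowsum(table$counts, group = lab)
  agg <- matrix(as.integer(agg), nrow = nrow(agg), dimnames = dimnames(agg))
  feature_table(agg)
}

#' Row-normalize counts to relative abundances
#'
#' @param table a [feature_table()] or counts matrix (features x samples).
#' @return numeric matrix of per-sample proportions (columns sum to 1).
#' @export
relative_abundance <- function(table) {
  m <- if (inherits(table, "feature_table")) table$counts else table
  sweep(m, 2L, colSums(m), "/")
}

#' Write a feature table as TSV plus feature FASTA
#'
#' @param table a [feature_table()].
#' @param tsv_path output TSV (features x samples, first column `feature_id`).
#' @param fasta_path optional output FASTA of feature sequences.
#' @return `tsv_path`, invisibly.
#' @export
write_feature_table <- function(table, tsv_path, fasta_path = NULL) {
  df <- data.frame(feature_id = rownames(table$counts), table$counts,
                   check.names = FALSE)
  utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(fasta_path) && !is.null(table$sequences)) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(table$sequences), fasta_path)
  }
  invisible(tsv_path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param tsv_path TSV path (first column `feature_id`).
#' @param fasta_path optional FASTA of feature sequences.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(tsv_path, fasta_path = NULL) {
  df <- utils::read.table(tsv_path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  seqs <- NULL
  if (!is.null(fasta_path)) {
    ss <- Biostrings::readDNAStringSet(fasta_path)
    seqs <- stats::setNames(as.character(ss), names(ss))
  }
  feature_table(m, seqs)
}
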