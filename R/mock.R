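# Mock-community expected composition and observed-vs-expected bias summaries.

#' Expected mock-community composition under equal-mass gDNA pooling
#'
#' With equal DNA mass per organism, the molar amount of each genome is
#' inversely proportional to its size, and the amplicon pool it contributes
#' is proportional to its rRNA copy number. The default (`basis =
#' "amplicon"`) therefore expects proportions proportional to
#' `copies / genome_size`, matching what a sequencer observes; `basis =
#' "genome"` gives molar genome (cell) proportions, proportional to
#' `1 / genome_size`.
#'
#' @param composition data.frame with columns `taxon`, `genome_size`
#'   (bp, > 0) and `rrna_copies` (>= 1); or a list of genome objects (sizes
#'   and copies taken from the generated truth).
#' @param basis `"amplicon"` or `"genome"`.
#' @return data.frame: `taxon`, `genome_size`, `rrna_copies`,
#'   `expected_proportion` (sums to 1).
#' @export
expected_composition <- function(composition, basis = c("amplicon", "genome")) {
  basis <- match.arg(basis)
  if (is.list(composition) && !is.data.frame(composition)) {
    composition <- do.call(rbind, lapply(composition, function(g) {
      data.frame(taxon = g$name, genome_size = sum(nchar(g$contigs)),
                 rrna_copies = sum(g$annotations$type == "rRNA_16S"))
    }))
  }
  req <- c("taxon", "genome_size", "rrna_copies")
  if (!all(req %in% names(composition)))
    stop("composition needs columns: ", paste(req, collapse = ", "))
  if (any(is.na(composition$genome_size)) || any(composition$genome_size <= 0))
    stop("genome_size must be positive")
  if (any(is.na(composition$rrna_copies)) || any(composition$rrna_copies < 1))
    stop("rrna_copies must be >= 1")
  w <- switch(basis,
              amplicon = composition$rrna_copies / composition$genome_size,
              genome = 1 / composition$genome_size)
  out <- composition[, req]
  out$expected_proportion <- w / sum(w)
  out[order(out$taxon), , drop = FALSE]
}

#' Reference composition of the 8-member mock community
#'
#' Genome sizes and rRNA operon copy numbers of the eight bacterial strains
#' of the standard equal-mass gDNA mock community, with the vendor's stated
#' 16S-level expected fractions for cross-checking.
#'
#' @return data.frame: `taxon`, `species`, `genome_size`, `rrna_copies`,
#'   `vendor_expected_16s`.
#' @export
mock_reference_composition <- function() {
  path <- system.file("extdata", "mock_community_reference.tsv",
                      package = "riboamp", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE)
}

#' Observed vs expected mock composition across replicates
#'
#' @param observed list of named per-replicate relative-abundance vectors
#'   (taxon -> proportion), or a matrix taxa x replicates.
#' @param expectations data.frame from [expected_composition()].
#' @return data.frame per taxon: `expected`, `observed_mean`, `observed_sd`
#'   (sample SD, n-1), `n_replicates`, `log2_bias`
#'   (`log2(observed_mean / expected)`); plus an `"other"` row collecting
#'   observed mass not mapping to any expected taxon.
#' @export
compare_observed_expected <- function(observed, expectations) {
  if (is.matrix(observed))
    observed <- lapply(seq_len(ncol(observed)), function(j) observed[, j])
  n <- length(observed)
  if (n == 0L) stop("need at least one replicate")
  taxa <- expectations$taxon
  obs <- vapply(observed, function(o) {
    v <- stats::setNames(rep(0, length(taxa)), taxa)
    known <- intersect(names(o), taxa)
    v[known] <- o[known]
    c(v, other = sum(o[setdiff(names(o), taxa)]))
  }, numeric(length(taxa) + 1L))
  mean_o <- rowMeans(obs)
  sd_o <- if (n > 1L) apply(obs, 1L, stats::sd) else rep(NA_real_, nrow(obs))
  exp_p <- c(stats::setNames(expectations$expected_proportion, taxa),
             other = 0)
  data.frame(taxon = names(mean_o),
             expected = unname(exp_p),
             observed_mean = unname(mean_o),
             observed_sd = unname(sd_o),
             n_replicates = n,
             log2_bias = unname(log2(mean_o / exp_p)),
             row.names = NULL)
}

#' Observed vs theoretical ASV counts per taxon
#'
#' Counts the distinct features assigned to each mock taxon and compares them
#' with the theoretical unique-amplicon count and the operon census.
#'
#' @param table a [feature_table()] restricted to mock samples.
#' @param assignments data.frame from [classify_lca()].
#' @param theoretical data.frame from [theoretical_asv_count()] (one design).
#' @param rank rank at which features are matched to mock taxa (default
#'   `"strain"`, i.e. the ribotype label used as the genome name).
#' @return data.frame per taxon: `observed_asvs`, `expected_asvs`, `copies`.
#' @export
asv_concordance <- function(table, assignments, theoretical,
                            rank = "strain") {
  stopifnot(inherits(table, "feature_table"))
  lab <- taxon_at_rank(assignments, rank)
  present <- rownames(table$counts)[rowSums(table$counts) > 0]
  lab <- lab[present]
  obs <- table(lab[!is.na(lab)])
  data.frame(taxon = theoretical$taxon,
             observed_asvs = as.integer(obs[theoretical$taxon]) |>
               (\(v) ifelse(is.na(v), 0L, v))(),
             expected_asvs = theoretical$unique_amplicons,
             copies = theoretical$operon_copies,
             row.names = NULL)
}
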