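# File-format helpers: FASTA/FASTQ via Biostrings, GFF3 truth annotations,
# distance matrices, newick trees.

#' Write a genome's contigs as FASTA
#'
#' @param genome a [generate_genome()] object or named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  contigs <- .as_contig_set(genome)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(contigs), path)
  invisible(path)
}

#' Read contigs from a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of contigs.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(ss), sub("\\s.*", "", names(ss)))
}

#' Write truth annotations as GFF3
#'
#' Internal 0-based half-open coordinates are converted to the 1-based
#' inclusive GFF3 convention.
#'
#' @param genome a [generate_genome()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth_gff3 <- function(genome, path) {
  ann <- genome$annotations
  lines <- c("##gff-version 3",
             sprintf("%s\triboamp\t%s\t%d\t%d\t.\t%s\t.\tID=%s;copy=%d;variant=%d",
                     ann$contig,
                     ifelse(ann$type %in% c("rRNA_16S", "rRNA_23S"), "rRNA",
                            ifelse(ann$type == "ITS", "misc_RNA", "region")),
                     ann$start + 1L, ann$end, ann$strand,
                     sprintf("%s_copy%d_%s", genome$name, ann$copy, ann$type),
                     ann$copy, ann$variant))
  # keep the part identity in a Name attribute
  lines[-1] <- paste0(lines[-1], ";Name=", ann$type)
  writeLines(lines, path)
  invisible(path)
}

#' Read rRNA annotations from a GFF3 file
#'
#' Uses `rtracklayer` when available; falls back to a minimal tab-split
#' reader otherwise. Returns the package's internal annotation layout
#' (0-based half-open `start`/`end`).
#'
#' @param path GFF3 file.
#' @return data.frame: `contig`, `start`, `end`, `strand`, `type` (with
#'   16S/23S rRNAs mapped to `rRNA_16S` / `rRNA_23S` by their `Name` or
#'   `product` attribute when present).
#' @export
read_rrna_gff3 <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "gff3")
    md <- S4Vectors::mcols(gr)
    nm <- if ("Name" %in% names(md)) as.character(md$Name) else
      if ("product" %in% names(md)) as.character(md$product) else
        as.character(md$type)
    df <- data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr),
                     strand = as.character(GenomicRanges::strand(gr)),
                     type = nm)
  } else {
    raw <- utils::read.table(path, sep = "\t", comment.char = "#",
                             quote = "", stringsAsFactors = FALSE)
    nm <- sub(".*Name=([^;]+).*", "\\1", raw$V9)
    nm[!grepl("Name=", raw$V9)] <- raw$V3[!grepl("Name=", raw$V9)]
    df <- data.frame(contig = raw$V1, start = raw$V4 - 1L, end = raw$V5,
                     strand = raw$V7, type = nm)
  }
  df$type[grepl("16S", df$type)] <- "rRNA_16S"
  df$type[grepl("23S", df$type)] <- "rRNA_23S"
  df
}

#' Write per-sample reads as FASTQ files
#'
#' One file per sample (`<sample>.fastq`) with constant quality scores, as
#' produced by an error-free simulator.
#'
#' @param reads the `reads` element of a [generate_reads()] result.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_reads_fastq <- function(reads, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (s in names(reads)) {
    x <- Biostrings::DNAStringSet(reads[[s]])
    q <- Biostrings::PhredQuality(
      vapply(nchar(reads[[s]]), function(n) strrep("I", n), character(1)))
    xq <- Biostrings::QualityScaledDNAStringSet(x, q)
    Biostrings::writeQualityScaledXStringSet(
      xq, file.path(dir, paste0(s, ".fastq")))
  }
  invisible(dir)
}

#' Read amplicon reads from FASTA/FASTQ files
#'
#' @param paths named vector of file paths (names = sample ids; basenames
#'   used otherwise).
#' @return named list of per-sample read character vectors.
#' @export
read_amplicon_reads <- function(paths) {
  if (is.null(names(paths)))
    names(paths) <- sub("\\.(fastq|fq|fasta|fa)$", "", basename(paths))
  lapply(paths, function(p) {
    fmt <- if (grepl("\\.(fastq|fq)$", p)) "fastq" else "fasta"
    ss <- Biostrings::readDNAStringSet(p, format = fmt)
    stats::setNames(as.character(ss), names(ss))
  })
}

#' Write a labeled square distance matrix as TSV
#'
#' @param d `dist` object or square matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  m <- as.matrix(d)
  df <- data.frame(sample = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
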