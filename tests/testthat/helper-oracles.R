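# Independent brute-force oracles and fixture builders shared by the tests.
# The oracles deliberately use different algorithms (character sets,
# recursive tip enumeration) from the package internals they check.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

rc_chr <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# position-by-position scan; template N matches nothing
oracle_primer_sites <- function(contig, primer, max_mismatch,
                                terminal_exact) {
  chars <- strsplit(contig, "")[[1]]
  L <- length(chars)
  rows <- list()
  for (strand in c("+", "-")) {
    pat <- strsplit(if (strand == "+") primer else rc_chr(primer), "")[[1]]
    m <- length(pat)
    if (L < m) next
    n_off <- L - m + 1L
    ok <- matrix(FALSE, m, n_off)
    for (j in seq_len(m))
      ok[j, ] <- chars[j:(L - m + j)] %in% IUPAC_SETS[[pat[j]]]
    mm <- colSums(!ok)
    tidx <- if (terminal_exact == 0L) integer(0)
            else if (strand == "+") (m - terminal_exact + 1L):m
            else seq_len(terminal_exact)
    term_ok <- if (length(tidx))
      colSums(!ok[tidx, , drop = FALSE]) == 0 else rep(TRUE, n_off)
    keep <- mm <= max_mismatch & term_ok
    if (any(keep))
      rows[[strand]] <- data.frame(position = which(keep) - 1L,
                                   strand = strand,
                                   mismatches = as.integer(mm[keep]))
  }
  out <- do.call(rbind, unname(rows))
  if (is.null(out))
    out <- data.frame(position = integer(0), strand = character(0),
                      mismatches = integer(0))
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# UniFrac by explicit enumeration of every branch's descendant tip set
oracle_unifrac <- function(tree, x, y, weighted = FALSE,
                           normalized = FALSE) {
  tips_below <- function(node) {
    if (node <= length(tree$tip.label)) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_below))
  }
  num <- 0; den <- 0
  xt <- sum(x); yt <- sum(y)
  for (k in seq_len(nrow(tree$edge))) {
    tl <- tips_below(tree$edge[k, 2])
    ax <- sum(x[intersect(names(x), tl)])
    ay <- sum(y[intersect(names(y), tl)])
    l <- tree$edge.length[k]
    if (!weighted) {
      if (xor(ax > 0, ay > 0)) num <- num + l
      if (ax > 0 || ay > 0) den <- den + l
    } else {
      num <- num + l * abs(ax / xt - ay / yt)
      den <- den + l * (ax / xt + ay / yt)
    }
  }
  if (!weighted) {
    if (den == 0) 0 else num / den
  } else if (normalized) {
    if (den == 0) 0 else num / den
  } else num
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

random_degenerate_primer <- function(n, n_degenerate = 2L) {
  base <- sample(c("A", "C", "G", "T"), n, TRUE)
  if (n_degenerate > 0L) {
    idx <- sample(seq_len(n - 3L), n_degenerate)  # keep the 3' end exact
    base[idx] <- sample(c("R", "Y", "S", "W", "K", "M", "N"), n_degenerate,
                        TRUE)
  }
  paste(base, collapse = "")
}

# a small mock-like panel of genomes with distinct genera
make_mock_genomes <- function(n_taxa = 4L, n_operons = 4L,
                              n_its_variants = 2L, genome_size = 40000L,
                              seed0 = 100L) {
  taxa <- LETTERS[seq_len(n_taxa)]
  gs <- lapply(seq_along(taxa), function(i) {
    generate_genome(genome_spec(
      lineage = make_lineage(paste0("Gen", taxa[i]),
                             species = paste0("Gen", taxa[i], "_sp"),
                             strain = taxa[i]),
      genome_size = genome_size, n_operons = n_operons,
      n_its_variants = n_its_variants, seed = seed0 + i))
  })
  names(gs) <- taxa
  gs
}

# plant the same substitution (in operon orientation) into every copy's 16S
# at a fixed 16S-relative offset; returns the edited genome object
plant_ssu_substitution <- function(genome, offset = 100L) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ann <- genome$annotations
  ssu <- ann[ann$type == "rRNA_16S", , drop = FALSE]
  chars <- strsplit(genome$contigs[["chr1"]], "")[[1]]
  # operon-strand base at this offset (identical across copies sharing the
  # 16S variant); mutate it consistently in every copy
  p1 <- if (ssu$strand[1] == "+") ssu$start[1] + offset
        else ssu$end[1] - 1L - offset
  b <- chars[p1 + 1L]
  if (ssu$strand[1] == "-") b <- comp[[b]]
  target <- setdiff(c("A", "C", "G", "T"), b)[1]
  for (i in seq_len(nrow(ssu))) {
    if (ssu$strand[i] == "+") {
      chars[ssu$start[i] + offset + 1L] <- target
    } else {
      chars[ssu$end[i] - offset] <- comp[[target]]
    }
  }
  genome$contigs[["chr1"]] <- paste(chars, collapse = "")
  genome
}
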