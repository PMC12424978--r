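# Synthetic genomes, communities, and amplicon reads with ground truth.

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# primer footprints inside the shipped scaffold (0-based half-open, relative
# to each part); divergence is never applied inside these windows unless
# mismatch injection is requested explicitly
SCAFFOLD_MASKS <- list(
  ssu = rbind(c(8L, 28L), c(515L, 535L), c(787L, 807L), c(1510L, 1529L)),
  its = matrix(integer(0), ncol = 2),
  lsu = rbind(c(540L, 560L))
)

#' The shipped synthetic operon scaffold
#'
#' A fixed rRNA operon template (16S, ITS, partial 23S) with the default
#' designs' primer-binding sites embedded exactly. The scaffold is synthetic:
#' primer sites are real universal primer targets resolved to concrete bases,
#' the remainder is fixed random sequence, so it is suitable for pipeline
#' validation but is not a biological reference.
#'
#' @return list with elements `ssu`, `its`, `lsu` (character) and `masks`
#'   (primer footprints per part, 0-based half-open).
#' @export
operon_scaffold <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    path <- system.file("extdata", "operon_scaffold_synthetic.fasta",
                        package = "riboamp", mustWork = TRUE)
    ss <- Biostrings::readDNAStringSet(path)
    cache <<- list(ssu = as.character(ss[["SSU_16S"]]),
                   its = as.character(ss[["ITS"]]),
                   lsu = as.character(ss[["LSU_23S_PREFIX"]]),
                   masks = SCAFFOLD_MASKS)
    cache
  }
})

# substitute bases at `rate` outside masked windows; returns the mutated string
mutate_outside <- function(seqstr, rate, masks = NULL) {
  if (rate <= 0) return(seqstr)
  n <- nchar(seqstr)
  eligible <- rep(TRUE, n)
  if (!is.null(masks) && nrow(masks)) {
    for (i in seq_len(nrow(masks)))
      eligible[(masks[i, 1] + 1L):masks[i, 2]] <- FALSE
  }
  idx <- which(eligible)
  k <- stats::rbinom(1L, length(idx), rate)
  if (k == 0L) return(seqstr)
  pos <- sample(idx, k)
  ch <- strsplit(seqstr, "", fixed = TRUE)[[1]]
  for (p in pos) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

#' Specification of a synthetic genome's rRNA operon architecture
#'
#' @param name genome (ribotype) label; defaults to the strain rank of
#'   `lineage`.
#' @param lineage named character vector of ranked labels
#'   (`domain` ... `strain`); see [make_lineage()].
#' @param genome_size total genome length in bp.
#' @param n_operons number of rRNA operon copies.
#' @param n_its_variants,n_16s_variants distinct ITS / 16S sequence variants
#'   among the copies (assigned round-robin).
#' @param divergence list of per-region substitution rates: `taxon` (whole
#'   operon vs the scaffold, drawn under `taxon_seed`), `strain_ssu` /
#'   `strain_its` (this genome vs the shared taxon template, drawn under
#'   `seed`; ribotypes of one species typically differ mostly in the ITS),
#'   and `ssu` / `its` (between intra-genome operon-copy variants).
#' @param non_contiguous if `TRUE`, an unrelated insertion of `insertion_bp`
#'   separates the 16S gene from the ITS/23S in every copy.
#' @param insertion_bp insertion length when `non_contiguous`.
#' @param seed RNG seed for this genome.
#' @param taxon_seed seed for the shared species-level operon template; two
#'   specs with the same `taxon_seed` but different `seed` model two strains
#'   of one species. Defaults to `seed`.
#' @return object of class `genome_spec`.
#' @export
genome_spec <- function(name = NULL, lineage, genome_size = 50000L,
                        n_operons = 4L, n_its_variants = 1L,
                        n_16s_variants = 1L,
                        divergence = list(taxon = 0.10,
                                          strain_ssu = 0, strain_its = 0.02,
                                          its = 0.02, ssu = 0.005),
                        non_contiguous = FALSE, insertion_bp = 0L,
                        seed = 1L, taxon_seed = NULL) {
  stopifnot(n_operons >= 1L,
            n_its_variants >= 1L, n_its_variants <= n_operons,
            n_16s_variants >= 1L, n_16s_variants <= n_operons,
            !non_contiguous || insertion_bp > 0L)
  if (is.null(name)) name <- unname(lineage[["strain"]])
  structure(list(name = name, lineage = lineage,
                 genome_size = as.integer(genome_size),
                 n_operons = as.integer(n_operons),
                 n_its_variants = as.integer(n_its_variants),
                 n_16s_variants = as.integer(n_16s_variants),
                 divergence = divergence,
                 non_contiguous = isTRUE(non_contiguous),
                 insertion_bp = as.integer(insertion_bp),
                 seed = as.integer(seed),
                 taxon_seed = as.integer(taxon_seed %||% seed)),
            class = "genome_spec")
}

#' Build a ranked lineage
#'
#' Upper ranks default to labels derived from the genus, which is adequate for
#' synthetic truth; supply them explicitly to model real taxonomies.
#'
#' @param genus,species,strain lower-rank labels.
#' @param domain,phylum,class_,order,family upper-rank labels.
#' @return named character vector over the eight ranks.
#' @export
make_lineage <- function(genus, species = paste0(genus, "_sp"),
                         strain = paste0(species, "_1"),
                         domain = "Bacteria",
                         phylum = paste0("phy_", genus),
                         class_ = paste0("cls_", genus),
                         order = paste0("ord_", genus),
                         family = paste0("fam_", genus)) {
  c(domain = domain, phylum = phylum, class = class_, order = order,
    family = family, genus = genus, species = species, strain = strain)
}

# distinct variants of a part sequence; variant 1 is the parent itself
.make_variants <- function(parent, n, rate, masks) {
  out <- character(n)
  out[1L] <- parent
  i <- 2L
  guard <- 0L
  while (i <= n) {
    v <- mutate_outside(parent, rate, masks)
    if (!v %in% out[seq_len(i - 1L)]) {
      out[i] <- v
      i <- i + 1L
    }
    guard <- guard + 1L
    if (guard > 1000L) stop("could not generate distinct variants; raise the divergence rate")
  }
  out
}

#' Generate a synthetic genome with planted rRNA operons
#'
#' Plants `n_operons` copies of the operon scaffold (after applying taxon- and
#' variant-level divergence outside primer footprints) into a random
#' background, on alternating random strands, and records every part in a
#' truth annotation table.
#'
#' @param spec a [genome_spec()].
#' @return object of class `riboamp_genome`: list with `name`, `lineage`,
#'   `contigs` (named character), `annotations` (data.frame with 0-based
#'   half-open `start`/`end`, `strand`, `type` in
#'   `{rRNA_16S, ITS, rRNA_23S, insertion}`, `copy`, `variant`), and `spec`.
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  sc <- operon_scaffold()
  dv <- spec$divergence
  # species-level template, shared by strains with the same taxon_seed
  tmpl <- with_seed(spec$taxon_seed, list(
    ssu = mutate_outside(sc$ssu, dv$taxon %||% 0, sc$masks$ssu),
    its = mutate_outside(sc$its, dv$taxon %||% 0, NULL),
    lsu = mutate_outside(sc$lsu, dv$taxon %||% 0, sc$masks$lsu)))
  with_seed(spec$seed, {
    ssu0 <- mutate_outside(tmpl$ssu, dv$strain_ssu %||% 0, sc$masks$ssu)
    its0 <- mutate_outside(tmpl$its, dv$strain_its %||% 0, NULL)
    lsu0 <- tmpl$lsu
    ssu_v <- .make_variants(ssu0, spec$n_16s_variants, dv$ssu %||% 0.005,
                            sc$masks$ssu)
    its_v <- .make_variants(its0, spec$n_its_variants, dv$its %||% 0.02, NULL)
    ins <- if (spec$non_contiguous) rand_dna(spec$insertion_bp) else ""

    n <- spec$n_operons
    parts_len <- c(ssu = nchar(ssu0), ins = nchar(ins), its = nchar(its0),
                   lsu = nchar(lsu0))
    op_len <- sum(parts_len)
    if (n * op_len + (n + 1L) * 200L > spec$genome_size)
      stop("operons do not fit in genome_size")
    gap <- (spec$genome_size - n * op_len) %/% (n + 1L)
    strands <- sample(c("+", "-"), n, replace = TRUE)

    pieces <- character(0)
    ann <- list()
    pos <- 0L
    for (i in seq_len(n)) {
      pieces <- c(pieces, rand_dna(gap))
      pos <- pos + gap
      sv <- ((i - 1L) %% spec$n_16s_variants) + 1L
      iv <- ((i - 1L) %% spec$n_its_variants) + 1L
      op <- paste0(ssu_v[sv], ins, its_v[iv], lsu0)
      # operon-relative part intervals (0-based half-open)
      rel <- list(
        rRNA_16S = c(0L, parts_len[["ssu"]]),
        insertion = c(parts_len[["ssu"]], parts_len[["ssu"]] + parts_len[["ins"]]),
        ITS = c(parts_len[["ssu"]] + parts_len[["ins"]],
                parts_len[["ssu"]] + parts_len[["ins"]] + parts_len[["its"]]),
        rRNA_23S = c(op_len - parts_len[["lsu"]], op_len))
      if (!spec$non_contiguous) rel$insertion <- NULL
      st <- strands[i]
      pieces <- c(pieces, if (st == "+") op else revcomp(op))
      for (ty in names(rel)) {
        u <- rel[[ty]][1]; v <- rel[[ty]][2]
        if (st == "+") {
          a <- pos + u; b <- pos + v
        } else {
          a <- pos + op_len - v; b <- pos + op_len - u
        }
        ann[[length(ann) + 1L]] <- data.frame(
          contig = "chr1", start = a, end = b, strand = st, type = ty,
          copy = i,
          variant = switch(ty, rRNA_16S = sv, ITS = iv, 1L))
      }
      pos <- pos + op_len
    }
    tail_len <- spec$genome_size - pos
    if (tail_len > 0L) pieces <- c(pieces, rand_dna(tail_len))
    genome <- paste(pieces, collapse = "")
    annotations <- do.call(rbind, ann)
    annotations <- annotations[order(annotations$start), , drop = FALSE]
    rownames(annotations) <- NULL
    structure(list(name = spec$name, lineage = spec$lineage,
                   contigs = c(chr1 = genome), annotations = annotations,
                   spec = spec, seed = spec$seed),
              class = "riboamp_genome")
  })
}

#' @export
print.riboamp_genome <- function(x, ...) {
  cat(sprintf("<riboamp_genome> %s: %d bp, %d rRNA operon copies\n",
              x$name, sum(nchar(x$contigs)),
              sum(x$annotations$type == "rRNA_16S")))
  invisible(x)
}

.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Generate a two-cohort community design with ground truth
#'
#' Cohort `B` proportions are the base composition with the supplied fold
#' changes applied to the affected taxa and renormalized. Per-sample
#' proportions optionally receive Dirichlet overdispersion around the cohort
#' mean.
#'
#' @param taxa character vector of taxon (genome) labels.
#' @param n_per_cohort samples per cohort (length 1 or 2).
#' @param base named base composition (defaults to uniform); any ordering.
#' @param fold named fold changes applied in cohort `B` (taxa not named get
#'   fold 1). All folds must be positive.
#' @param overdispersion Dirichlet concentration parameter (total); `NULL`
#'   for exact cohort proportions in every sample.
#' @param seed RNG seed.
#' @return object of class `community_truth`: `proportions` (samples x taxa),
#'   `cohort` (factor), `effect` (the fold vector), `seed`.
#' @export
generate_community <- function(taxa, n_per_cohort = 12L, base = NULL,
                               fold = NULL, overdispersion = NULL,
                               seed = 1L) {
  k <- length(taxa)
  if (is.null(base)) base <- stats::setNames(rep(1 / k, k), taxa)
  base <- base[taxa] / sum(base[taxa])
  f <- stats::setNames(rep(1, k), taxa)
  if (!is.null(fold)) {
    stopifnot(all(fold > 0), all(names(fold) %in% taxa))
    f[names(fold)] <- fold
  }
  pB <- base * f
  pB <- pB / sum(pB)
  if (length(n_per_cohort) == 1L) n_per_cohort <- rep(n_per_cohort, 2L)
  n <- sum(n_per_cohort)
  cohort <- factor(rep(c("A", "B"), n_per_cohort))
  with_seed(seed, {
    props <- matrix(NA_real_, n, k, dimnames = list(
      sprintf("S%02d", seq_len(n)), taxa))
    for (i in seq_len(n)) {
      mu <- if (cohort[i] == "A") base else pB
      props[i, ] <- if (is.null(overdispersion)) mu
                    else .rdirichlet1(mu * overdispersion)
    }
    structure(list(proportions = props, cohort = cohort,
                   effect = f, base = base, seed = seed),
              class = "community_truth")
  })
}

# map amplicon hits to operon copies of a generated genome by coordinate
# overlap with the truth annotations
.hits_to_copies <- function(genome, hits) {
  ann <- genome$annotations
  vapply(seq_len(nrow(hits)), function(i) {
    ov <- ann$contig == hits$contig[i] &
      ann$start < hits$insert_end[i] & ann$end > hits$insert_start[i]
    cp <- unique(ann$copy[ov])
    if (length(cp) == 1L) cp else NA_integer_
  }, integer(1L))
}

# per-genome amplifiable inserts under a design: copy id -> insert sequence
.amplifiable_inserts <- function(genome, design, scan_ceiling = 10000L) {
  hits <- in_silico_pcr(genome, design, scan_ceiling = scan_ceiling)
  hits <- hits[hits$passed_length_filter, , drop = FALSE]
  if (!nrow(hits)) return(character(0))
  cp <- .hits_to_copies(genome, hits)
  stats::setNames(hits$sequence, cp)
}

#' Simulate amplicon reads from a community
#'
#' Reads are drawn per sample: taxon according to the sample's (optionally
#' bias-distorted) proportions, operon copy uniformly among the taxon's
#' amplifiable copies under the design, and the read sequence is the copy's
#' insert with iid substitution errors at `error_rate`. Taxa with no
#' amplifiable copy under the design produce no reads (primer/architecture
#' dropout); the sample's depth is filled by the remaining taxa, and dropped
#' taxa are recorded.
#'
#' @param genomes named list of [generate_genome()] objects, names = taxa of
#'   `truth`.
#' @param truth a [generate_community()] object.
#' @param design an [amplicon_design()].
#' @param depth reads per sample.
#' @param error_rate per-base substitution probability in `[0, 0.05]`.
#' @param amplification_bias named per-taxon efficiency multipliers
#'   (default 1), applied to sampling proportions and renormalized.
#' @param seed RNG seed.
#' @return list with `reads` (per-sample named character vectors),
#'   `provenance` (data.frame: `read_id`, `sample`, `genome`, `copy`),
#'   `dropped` (taxa with no amplifiable copy), `design`, `seed`.
#' @export
generate_reads <- function(genomes, truth, design, depth = 5000L,
                           error_rate = 0, amplification_bias = NULL,
                           seed = 1L) {
  stopifnot(error_rate >= 0, error_rate <= 0.05)
  taxa <- colnames(truth$proportions)
  stopifnot(all(taxa %in% names(genomes)))
  inserts <- lapply(genomes[taxa], .amplifiable_inserts, design = design)
  dropped <- taxa[vapply(inserts, length, 1L) == 0L]
  if (length(dropped))
    message("taxa with no amplifiable copy under ", design$region_label,
            " omitted: ", paste(dropped, collapse = ", "))
  keep <- setdiff(taxa, dropped)
  if (!length(keep)) stop("no taxon is amplifiable under this design")
  bias <- stats::setNames(rep(1, length(taxa)), taxa)
  if (!is.null(amplification_bias))
    bias[names(amplification_bias)] <- amplification_bias
  with_seed(seed, {
    reads <- list()
    prov <- list()
    for (s in rownames(truth$proportions)) {
      p <- truth$proportions[s, keep] * bias[keep]
      p <- p / sum(p)
      n_tax <- as.vector(stats::rmultinom(1L, depth, p))
      seqs <- character(depth); gsrc <- character(depth); csrc <- integer(depth)
      off <- 0L
      for (ti in seq_along(keep)) {
        nt <- n_tax[ti]
        if (nt == 0L) next
        ins <- inserts[[keep[ti]]]
        ci <- sample.int(length(ins), nt, replace = TRUE)
        seqs[(off + 1L):(off + nt)] <- unname(ins[ci])
        gsrc[(off + 1L):(off + nt)] <- keep[ti]
        csrc[(off + 1L):(off + nt)] <- as.integer(names(ins)[ci])
        off <- off + nt
      }
      if (error_rate > 0) {
        nerr <- stats::rbinom(depth, nchar(seqs), error_rate)
        for (ri in which(nerr > 0L)) {
          ch <- strsplit(seqs[ri], "", fixed = TRUE)[[1]]
          pos <- sample.int(length(ch), nerr[ri])
          for (p2 in pos) ch[p2] <- sample(setdiff(c("A","C","G","T"), ch[p2]), 1L)
          seqs[ri] <- paste(ch, collapse = "")
        }
      }
      ids <- sprintf("%s_r%05d", s, seq_len(depth))
      reads[[s]] <- stats::setNames(seqs, ids)
      prov[[s]] <- data.frame(read_id = ids, sample = s, genome = gsrc,
                              copy = csrc)
    }
    list(reads = reads, provenance = do.call(rbind, unname(prov)),
         dropped = dropped, design = design$region_label, seed = seed)
  })
}

#' Benchmark two-cohort community for design comparison
#'
#' A fixed study design exercising all four beta-diversity metrics: five
#' common taxa (4 operons, 2 ITS variants each) plus one rare taxon at 0.11%
#' with 12 operons carrying 12 ITS variants, so its amplicon variants sit
#' near the per-sample detection limit. The cohort effect is a three-fold
#' increase of the rare taxon and of one 5% taxon: the abundance shift drives
#' Bray-Curtis and weighted UniFrac, the detection-limit shift drives Jaccard
#' and unweighted UniFrac.
#'
#' @param seed RNG seed offset for genome construction.
#' @return list: `genomes`, `base` (named composition), `fold` (cohort-B
#'   fold changes).
#' @export
benchmark_community <- function(seed = 610L) {
  taxa <- c("A", "B", "C", "D", "E")
  genomes <- lapply(seq_along(taxa), function(i) {
    generate_genome(genome_spec(
      lineage = make_lineage(paste0("Gen", taxa[i]),
                             species = paste0("Gen", taxa[i], "_sp"),
                             strain = taxa[i]),
      genome_size = 40000L, n_operons = 4L, n_its_variants = 2L,
      seed = seed + i))
  })
  names(genomes) <- taxa
  genomes$R <- generate_genome(genome_spec(
    lineage = make_lineage("GenR", strain = "R"), genome_size = 130000L,
    n_operons = 12L, n_its_variants = 12L, seed = seed + 6L))
  list(genomes = genomes,
       base = c(A = 0.32, B = 0.28, C = 0.2, D = 0.1489, E = 0.05,
                R = 0.0011),
       fold = c(R = 3, E = 3))
}
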