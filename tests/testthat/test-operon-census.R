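designs <- default_designs()

test_that("census recovers the planted operon architecture exactly", {
  for (n_op in c(3L, 10L)) {
    sp <- genome_spec(lineage = make_lineage("GenX"), genome_size = 70000,
                      n_operons = n_op, n_its_variants = min(3L, n_op),
                      seed = 7 + n_op)
    g <- generate_genome(sp)
    cen <- locate_operons(g)
    expect_equal(nrow(cen), n_op)
    expect_true(all(cen$contiguous))
    expect_true(all(cen$gap_bp == nchar(operon_scaffold()$its)))
    ann <- g$annotations
    expect_setequal(cen$ssu_start,
                    ann$start[ann$type == "rRNA_16S"])
  }
})

test_that("a planted insertion between 16S and 23S breaks contiguity", {
  g <- generate_genome(genome_spec(
    lineage = make_lineage("GenNC"), genome_size = 70000, n_operons = 2,
    non_contiguous = TRUE, insertion_bp = 5000, seed = 9))
  cen <- locate_operons(g)
  expect_equal(nrow(cen), 2L)
  expect_false(any(cen$contiguous))
  expect_true(all(cen$gap_bp > 2000))
  # a permissive gap threshold restores contiguity (threshold is a policy)
  cen2 <- locate_operons(g, gap_threshold = 10000)
  expect_true(all(cen2$contiguous))
})

test_that("unpaired 16S copies get the infinite-gap sentinel", {
  g <- generate_genome(genome_spec(
    lineage = make_lineage("GenU"), genome_size = 40000, n_operons = 2,
    seed = 13))
  ann <- g$annotations
  ann <- ann[!(ann$type == "rRNA_23S" & ann$copy == 1L), , drop = FALSE]
  cen <- locate_operons(g, annotations = ann)
  expect_equal(nrow(cen), 2L)
  bad <- cen[!cen$contiguous, ]
  expect_equal(nrow(bad), 1L)
  expect_true(is.infinite(bad$gap_bp))
  expect_error(locate_operons(g, annotations = transform(ann, contig = "nope")),
               "unknown contig")
})

test_that("primer-driven census approximates the annotation-driven one", {
  g <- generate_genome(genome_spec(
    lineage = make_lineage("GenP"), genome_size = 60000, n_operons = 5,
    seed = 17))
  cen_a <- locate_operons(g)
  cen_p <- locate_operons(g$contigs, mode = "primer")
  expect_equal(nrow(cen_p), nrow(cen_a))
  expect_true(all(cen_p$contiguous))
  # 16S interval approximated by the full-16S primer footprints
  expect_true(all(abs(cen_p$ssu_start - cen_a$ssu_start) <= 30))
})

test_that("theoretical ASV counts follow the planted variant structure", {
  # identical copies -> one amplicon
  g1 <- generate_genome(genome_spec(
    lineage = make_lineage("GenI"), genome_size = 70000, n_operons = 10,
    n_its_variants = 1, seed = 23))
  r1 <- theoretical_asv_count(list(g1), designs$STRAINID)
  expect_equal(r1$operon_copies, 10L)
  expect_equal(r1$unique_amplicons, 1L)
  # 3 ITS variants resolved by the long design only
  g3 <- generate_genome(genome_spec(
    lineage = make_lineage("GenV"), genome_size = 70000, n_operons = 10,
    n_its_variants = 3, seed = 29))
  expect_equal(theoretical_asv_count(list(g3), designs$STRAINID)$unique_amplicons, 3L)
  expect_equal(theoretical_asv_count(list(g3), designs$V4)$unique_amplicons, 1L)
  expect_equal(theoretical_asv_count(list(g3), designs$FULL16S)$unique_amplicons, 1L)
})

test_that("theoretical counts match direct annotation slicing on random genomes", {
  # independent oracle: slice the 16S..23S-primer-site span from the truth
  # annotations and count distinct design inserts set-wise
  set.seed(31)
  for (rep in 1:8) {
    g <- generate_genome(genome_spec(
      lineage = make_lineage(paste0("GenR", rep)), genome_size = 60000,
      n_operons = sample(2:8, 1), n_its_variants = sample(1:2, 1),
      n_16s_variants = sample(1:2, 1), seed = 1000 + rep))
    for (dn in c("V4", "STRAINID")) {
      d <- designs[[dn]]
      ann <- g$annotations
      seqs <- character(0)
      for (cp in unique(ann$copy)) {
        a <- ann[ann$copy == cp, ]
        lo <- min(a$start); hi <- max(a$end)
        op <- substr(g$contigs[["chr1"]], lo + 1, hi)
        if (a$strand[1] == "-") op <- revcomp(op)
        h <- oracle_primer_sites(op, d$primers$forward, d$primers$max_mismatch,
                                 d$primers$terminal_exact)
        h2 <- oracle_primer_sites(op, d$primers$reverse, d$primers$max_mismatch,
                                  d$primers$terminal_exact)
        fp <- h$position[h$strand == "+"][1]
        rp <- h2$position[h2$strand == "-"][1]
        ins <- substr(op, fp + nchar(d$primers$forward) + 1, rp)
        if (nchar(ins) >= d$min_length && nchar(ins) <= d$max_length)
          seqs <- c(seqs, ins)
      }
      expect_equal(theoretical_asv_count(list(g), d)$unique_amplicons,
                   length(unique(seqs)), info = paste(rep, dn))
    }
  }
})

test_that("nested designs give monotone non-decreasing ASV counts", {
  set.seed(37)
  for (rep in 1:6) {
    g <- generate_genome(genome_spec(
      lineage = make_lineage(paste0("GenM", rep)), genome_size = 70000,
      n_operons = sample(4:10, 1), n_its_variants = sample(1:4, 1),
      n_16s_variants = sample(1:3, 1), seed = 2000 + rep))
    u <- vapply(c("V4", "FULL16S", "STRAINID"), function(dn)
      theoretical_asv_count(list(g), designs[[dn]])$unique_amplicons,
      integer(1))
    expect_true(all(diff(u) >= 0), info = paste(u, collapse = ","))
    v13 <- theoretical_asv_count(list(g), designs$V1V3)$unique_amplicons
    expect_lte(v13, u[["FULL16S"]])
  }
})

test_that("compatibility statuses partition the census", {
  g_ok <- generate_genome(genome_spec(
    lineage = make_lineage("GenO"), genome_size = 50000, n_operons = 4,
    seed = 41))
  g_nc <- generate_genome(genome_spec(
    lineage = make_lineage("GenN"), genome_size = 70000, n_operons = 3,
    non_contiguous = TRUE, insertion_bp = 5000, seed = 43))
  rep_tab <- design_compatibility_report(list(g_ok, g_nc), designs)
  # every (taxon, design) has exactly one status per copy
  counts <- table(rep_tab$taxon, rep_tab$design)
  expect_true(all(counts[rownames(counts) == g_ok$name, ] == 4L))
  expect_true(all(counts[rownames(counts) == g_nc$name, ] == 3L))
  # the long design is excluded by product length for the split operon
  nc_long <- rep_tab[rep_tab$taxon == g_nc$name &
                       rep_tab$design == "STRAINID", ]
  expect_true(all(nc_long$status == "length"))
  nc_short <- rep_tab[rep_tab$taxon == g_nc$name & rep_tab$design == "V1V3", ]
  expect_true(all(nc_short$status == "amplifiable"))
})

test_that("a heavily mutated reverse-primer site is excluded as mismatch", {
  g <- generate_genome(genome_spec(
    lineage = make_lineage("GenMM"), genome_size = 40000, n_operons = 2,
    seed = 47))
  # mutate 4 bases of the long design's reverse-primer footprint in each 23S
  ann <- g$annotations
  lsu <- ann[ann$type == "rRNA_23S", ]
  chars <- strsplit(g$contigs[["chr1"]], "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in seq_len(nrow(lsu))) {
    for (off in c(542L, 546L, 550L, 554L)) {  # inside the [540,560) footprint
      pos <- if (lsu$strand[i] == "+") lsu$start[i] + off + 1L
             else lsu$end[i] - off
      chars[pos] <- comp[[chars[pos]]]
    }
  }
  g$contigs[["chr1"]] <- paste(chars, collapse = "")
  rep_tab <- design_compatibility_report(list(g), designs["STRAINID"])
  expect_true(all(rep_tab$status == "mismatch"))
  # the unrelated short design is unaffected
  rep_v4 <- design_compatibility_report(list(g), designs["V4"])
  expect_true(all(rep_v4$status == "amplifiable"))
})
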