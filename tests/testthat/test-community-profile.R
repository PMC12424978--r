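designs <- default_designs()

test_that("exact dereplication counts reads per distinct sequence", {
  reads <- list(s1 = rep("ACGT", 100))
  ft <- dereplicate_asvs(reads)
  expect_equal(dim(ft), c(1L, 1L))
  expect_equal(unname(ft$counts[1, 1]), 100L)
  expect_identical(unname(ft$sequences), "ACGT")
  # min_total_count threshold
  reads2 <- list(s1 = c(rep("AAAA", 5), rep("CCCC", 3), "GGGG"))
  ft2 <- dereplicate_asvs(reads2, min_total_count = 2)
  expect_equal(nrow(ft2$counts), 2L)
  expect_setequal(unname(ft2$sequences), c("AAAA", "CCCC"))
  # empty input and NA reads
  expect_equal(nrow(dereplicate_asvs(list(s1 = NA_character_))$counts), 0L)
})

test_that("error-free reads dereplicate losslessly to the theoretical set", {
  gs <- make_mock_genomes(n_taxa = 3L, seed0 = 300L)
  tr <- generate_community(names(gs), n_per_cohort = 2, seed = 5)
  rd <- generate_reads(gs, tr, designs$STRAINID, depth = 400, seed = 6)
  ft <- dereplicate_asvs(rd$reads)
  theo <- unlist(lapply(gs, function(g)
    theoretical_asv_count(list(g), designs$STRAINID)$amplicon_sequences[[1]]))
  expect_setequal(unname(ft$sequences), unname(theo))
})

test_that("LCA classification resolves to the deepest common rank", {
  ref <- amplicon_reference(
    ids = c("r1", "r2", "r3"),
    sequences = c("AAAAAAAAAA", "AAAAAAAAAT", "GGGGGGGGGG"),
    lineages = c("B;p1;c1;o1;f1;g1;s1;st1",
                 "B;p1;c1;o1;f1;g1;s2;st2",
                 "B;p2;c2;o2;f2;g2;s3;st3"))
  # exact unique match -> full strain lineage
  a1 <- classify_lca(c(f1 = "AAAAAAAAAA"), ref, max_distance = 0)
  expect_identical(a1$deepest_rank, "strain")
  expect_identical(a1$lineage, "B;p1;c1;o1;f1;g1;s1;st1")
  # equidistant from two references sharing genus -> genus
  a2 <- classify_lca(c(f2 = "AAAAAAAAAC"), ref, max_distance = 1)
  expect_identical(a2$deepest_rank, "genus")
  # nothing within reach -> unclassified
  a3 <- classify_lca(c(f3 = "TTTTTTTTTT"), ref, max_distance = 2)
  expect_identical(a3$deepest_rank, "unclassified")
  # length-tolerant matching via edit distance
  a4 <- classify_lca(c(f4 = "GGGGGGGGG"), ref, max_distance = 1)
  expect_identical(a4$deepest_rank, "strain")
  expect_error(amplicon_reference("x", "AA", "B;;g"), "malformed")
})

test_that("classification is invariant to reference ordering", {
  gs <- make_mock_genomes(n_taxa = 3L, seed0 = 310L)
  ref <- reference_from_genomes(gs, designs$V4)
  tr <- generate_community(names(gs), n_per_cohort = 1, seed = 8)
  rd <- generate_reads(gs, tr, designs$V4, depth = 300, seed = 9)
  ft <- dereplicate_asvs(rd$reads)
  a <- classify_lca(ft, ref)
  perm <- ref[rev(seq_len(nrow(ref))), ]
  b <- classify_lca(ft, amplicon_reference(perm$id, perm$sequence,
                                           perm$lineage))
  expect_identical(a, b)
})

test_that("classification rates are read-weighted per sample", {
  cnt <- matrix(c(80L, 20L, 50L, 50L), 2, 2,
                dimnames = list(c("ASV1", "ASV2"), c("s1", "s2")))
  ft <- feature_table(cnt, c(ASV1 = "AAAA", ASV2 = "CCCC"))
  asn <- data.frame(feature_id = c("ASV1", "ASV2"),
                    lineage = c("B;p;c;o;f;g", ""),
                    deepest_rank = c("genus", "unclassified"))
  cr <- classification_rate(ft, asn, "genus")
  expect_equal(unname(cr$per_sample), c(0.8, 0.5))
  expect_equal(cr$median, 0.65)
  expect_equal(classification_rate(ft, asn, "domain")$median, 0.65)
  # all features classified to strain -> rate 1 at every rank
  asn2 <- data.frame(feature_id = c("ASV1", "ASV2"),
                     lineage = rep("B;p;c;o;f;g;s;st", 2),
                     deepest_rank = rep("strain", 2))
  for (rk in c("genus", "species", "strain"))
    expect_equal(unname(classification_rate(ft, asn2, rk)$per_sample),
                 c(1, 1))
})

test_that("strain resolution increases with amplicon span", {
  # A1/A2 differ only in the ITS; B1/B2 differ at one 16S site outside the
  # V4 window; C is unambiguous. Longer amplicons resolve more strains.
  mkspec <- function(strain, species, seed, taxon_seed)
    genome_spec(lineage = make_lineage(paste0("Gen", substr(species, 1, 1)),
                                       species = species, strain = strain),
                genome_size = 40000, n_operons = 3, seed = seed,
                taxon_seed = taxon_seed,
                divergence = list(taxon = 0.10, strain_ssu = 0,
                                  strain_its = 0.03, its = 0.02, ssu = 0.005))
  gs <- list(A1 = generate_genome(mkspec("A1", "Asp", 61, 600)),
             A2 = generate_genome(mkspec("A2", "Asp", 62, 600)),
             B1 = generate_genome(mkspec("B1", "Bsp", 63, 700)),
             C1 = generate_genome(mkspec("C1", "Csp", 65, 800)))
  gs$B2 <- plant_ssu_substitution(gs$B1, offset = 100L)
  gs$B2$name <- "B2"
  gs$B2$lineage[["strain"]] <- "B2"
  taxa <- names(gs)
  tr <- generate_community(taxa, n_per_cohort = 2, seed = 71)
  rates <- vapply(c("V4", "FULL16S", "STRAINID"), function(dn) {
    d <- designs[[dn]]
    rd <- generate_reads(gs, tr, d, depth = 500, seed = 72)
    ft <- dereplicate_asvs(rd$reads)
    ref <- reference_from_genomes(gs, d)
    asn <- classify_lca(ft, ref)
    classification_rate(ft, asn, "strain")$median
  }, numeric(1))
  expect_lt(rates[["V4"]], rates[["FULL16S"]])
  expect_lt(rates[["FULL16S"]], rates[["STRAINID"]])
  expect_equal(rates[["STRAINID"]], 1)
})

test_that("rarefaction subsamples without replacement to exact depth", {
  cnt <- matrix(c(900L, 100L, 40L, 30L), 2, 2,
                dimnames = list(c("ASV1", "ASV2"), c("big", "small")))
  ft <- feature_table(cnt, c(ASV1 = "AAAA", ASV2 = "CCCC"))
  expect_warning(rf <- rarefy(ft, 100, seed = 1), "small")
  expect_equal(colnames(rf$counts), "big")
  expect_equal(unname(colSums(rf$counts)), 100)
  # sample total == depth -> counts unchanged
  rf2 <- suppressWarnings(rarefy(ft, 70, seed = 1))
  expect_equal(unname(rf2$counts[, "small"]), c(40L, 30L))
  expect_error(rarefy(ft, 0), "positive")
  # deterministic under a fixed seed
  expect_identical(suppressWarnings(rarefy(ft, 100, seed = 9))$counts,
                   suppressWarnings(rarefy(ft, 100, seed = 9))$counts)
})

test_that("rarefied counts follow the hypergeometric expectation", {
  cnt <- matrix(c(900L, 100L), 2, 1,
                dimnames = list(c("ASV1", "ASV2"), "s"))
  ft <- feature_table(cnt, c(ASV1 = "AAAA", ASV2 = "CCCC"))
  n_rep <- 3000
  draws <- vapply(seq_len(n_rep), function(i)
    rarefy(ft, 100, seed = i)$counts[1, 1], integer(1))
  # hypergeometric mean 90, variance 100*.9*.1*(900/999)
  se <- sqrt(100 * 0.9 * 0.1 * (900 / 999) / n_rep)
  expect_lt(abs(mean(draws) - 90), 3 * se)
})

test_that("taxon aggregation conserves reads and pools the unclassified", {
  set.seed(53)
  for (rep in 1:5) {
    k <- sample(3:8, 1); s <- sample(2:4, 1)
    cnt <- matrix(rpois(k * s, 20), k, s,
                  dimnames = list(paste0("ASV", 1:k), paste0("smp", 1:s)))
    cnt[1, ] <- cnt[1, ] + 1L  # keep feature 1 nonzero
    ft <- feature_table(cnt, setNames(vapply(1:k, function(i) random_dna(8),
                                             ""), paste0("ASV", 1:k)))
    gen <- sample(c("g1", "g2", NA), k, TRUE)
    asn <- data.frame(
      feature_id = paste0("ASV", 1:k),
      lineage = ifelse(is.na(gen), "",
                       paste("B", "p", "c", "o", "f", gen, sep = ";")),
      deepest_rank = ifelse(is.na(gen), "unclassified", "genus"))
    agg <- aggregate_taxa(ft, asn, "genus")
    expect_equal(colSums(agg$counts), colSums(ft$counts))
    if (any(is.na(gen)))
      expect_true("unclassified" %in% rownames(agg$counts))
    ra <- relative_abundance(agg)
    expect_equal(unname(colSums(ra)), rep(1, s))
  }
  # two features of one genus sum
  cnt <- matrix(c(3L, 7L), 2, 1, dimnames = list(c("ASV1", "ASV2"), "s1"))
  ft <- feature_table(cnt, c(ASV1 = "AA", ASV2 = "CC"))
  asn <- data.frame(feature_id = c("ASV1", "ASV2"),
                    lineage = rep("B;p;c;o;f;g9", 2),
                    deepest_rank = rep("genus", 2))
  expect_equal(unname(aggregate_taxa(ft, asn, "genus")$counts["g9", ]), 10L)
  expect_equal(unname(relative_abundance(matrix(c(2, 2), 2, 1,
    dimnames = list(c("a", "b"), "s")))[, 1]), c(0.5, 0.5))
})

test_that("feature tables round-trip through TSV + FASTA", {
  gs <- make_mock_genomes(n_taxa = 2L, seed0 = 320L)
  tr <- generate_community(names(gs), n_per_cohort = 1, seed = 3)
  rd <- generate_reads(gs, tr, designs$V4, depth = 200, seed = 4)
  ft <- dereplicate_asvs(rd$reads)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_feature_table(ft, tsv, fa)
  back <- read_feature_table(tsv, fa)
  expect_equal(back$counts, ft$counts)
  expect_identical(back$sequences, ft$sequences)
})
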