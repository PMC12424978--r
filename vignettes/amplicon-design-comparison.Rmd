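---
title: "Comparing rRNA amplicon designs with riboamp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing rRNA amplicon designs with riboamp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboamp)
```

## The problem

Most microbiome surveys sequence a short hypervariable window of the 16S
rRNA gene (V1-V3 for saliva, V4 for stool), which rarely resolves taxa below
the genus. Long-read platforms make two longer targets practical: the full
16S gene (~1.5 kb) and an operon-spanning amplicon (~2.5 kb) covering the
16S gene, the internal transcribed spacer (ITS), and the 5' portion of the
23S gene. Because bacteria carry several rRNA operon copies whose sequences
diverge mostly in the ITS, the long amplicon can resolve *ribotypes* —
variants defined by their set of operon sequences — which is what
"strain-level" classification from rRNA data actually means.

`riboamp` provides the machinery to compare such designs quantitatively:
in-silico PCR, operon census with theoretical ASV prediction, ASV feature
tables with LCA classification, four beta-diversity metrics with ordination
and PERMANOVA, mock-community bias evaluation, and a seeded synthetic-data
generator so that every claim is testable without downloads.

## Amplicon designs and primer matching

A design is a primer pair plus a length-bound policy. The defaults are the
universal pairs 27F/534R (V1-V3), 515F/806R (V4), 27F/1492R (full 16S), and
a long design pairing 27F with a 23S reverse primer. The commercial
long-amplicon kit does not publish its primer sequences, so the default 23S
reverse primer is a synthetic stand-in embedded exactly in the shipped
operon scaffold; every sequence and bound can be overridden via
`amplicon_design()` or a YAML config (`read_design_config()`).

Matching is asymmetric, mirroring annealing: a primer degeneracy code (e.g.
`M = {A,C}`) matches any base of its set, while an ambiguous template base
(`N`) matches nothing. The matching policy has three knobs, all per primer:

* `max_mismatch` (default 2) — mismatches tolerated across the footprint;
* `terminal_exact` (default 3) — 3'-terminal bases that must match exactly,
  since 3' mismatches are what actually abort extension;
* length bounds — `[100, 600]` bp for the short designs, `[1000, 1800]` for
  full 16S, `[1000, 3500]` for the long design.

`in_silico_pcr()` pairs each forward site with the nearest compatible
reverse site up to a 10 kb scan ceiling and reports every product,
including those outside the length bounds (`passed_length_filter = FALSE`).
Keeping over-long products visible is deliberate: a non-contiguous operon
(genes inserted between 16S and 23S, as in some Saccharibacteria) yields a
~7 kb product that real amplification conditions cannot produce, and the
report shows *why* the taxon drops out rather than silently losing it.

Coordinates are 0-based half-open internally; GFF3 output is 1-based
inclusive. Amplicon sequences are inter-primer inserts (primer regions
excluded), matching the primer-removal convention of ASV workflows.

### In-silico trimming

`trim_to_subregion()` derives short-design reads from long-design reads by
locating the internal primer sites, enabling like-for-like comparisons on
identical molecules. One subtlety: V1-V3 and full 16S share the 27F forward
primer with the long design, so on a primer-free insert their forward site
was removed along with the parent primer. Passing `parent_design` anchors
such trims at the read's 5' end, which is exactly where that junction lies.

## Operon census and theoretical ASV counts

`locate_operons()` enumerates 16S instances and pairs each with the nearest
same-strand downstream 23S. A copy is *contiguous* when the 16S-end to
23S-start gap is at most `gap_threshold` (default 2,000 bp — comfortably
above typical ITS lengths, below any gene-sized insertion; the choice is
exposed because no universal threshold exists). Unpaired copies carry an
infinite-gap sentinel. Annotation-driven mode is preferred; the
primer-driven fallback approximates the 23S start by the long design's
reverse-primer site and widens the threshold by the site's nominal offset
into the gene (600 bp), and should be treated as approximate.

`theoretical_asv_count()` extracts each design's insert from every
amplifiable copy and counts distinct sequences — the number of ASVs an
error-free workflow would recover. `design_compatibility_report()` assigns
every copy exactly one status per design (`amplifiable`, `length`,
`non_contiguous`, `mismatch`), and the statuses partition the census, so
nothing is double-counted or lost.

## Feature tables, classification, rarefaction

`dereplicate_asvs()` replaces model-based denoising with exact
dereplication. This is the package's main deliberate divergence from
DADA2-based pipelines: the synthetic reads are error-free by default (or
carry iid substitutions), so denoising would add an error model without
adding information. Consequences: on error-free reads the pipeline is
lossless (observed ASVs equal theoretical ASVs exactly), and with
substitution errors the `min_total_count` filter plays the role of
abundance-based cleanup. Conclusions about DADA2's behaviour on real
error profiles are out of scope.

`classify_lca()` assigns each feature the lowest common ancestor of its
best reference matches (substitution-only Hamming distance on equal
lengths, exact edit distance for length differences up to 10 bp, default
acceptance radius 1% of the feature length). "Strain" means the reference's
ribotype label. `classification_rate()` reports the read-weighted
proportion classified at or below a rank, per sample with the median across
samples, mirroring how classification depth is compared between designs.

`rarefy()` subsamples without replacement (multivariate hypergeometric) to
an even depth, dropping shallower samples with a warning; it is
deterministic given its seed.

## Beta diversity, trees, ordination, PERMANOVA

The four metrics are implemented from their definitions: Bray-Curtis
(`sum|x-y| / sum(x+y)`), Jaccard on supports, and the two UniFrac variants
on a rooted tree — unweighted as the unique-branch-length fraction
restricted to branches present in either sample, weighted as the classic
non-normalized variant `sum_b l_b |A_b/A_T - B_b/B_T|` (the normalized
variant is a flag). Each is verified in the test suite against independent
oracles: a branch-enumeration UniFrac oracle on random trees (agreement to
1e-12) and the standard community-ecology implementations.

Trees come from neighbor joining on p-distances (global alignment when
lengths differ), negative branch lengths clamped to zero, midpoint-rooted,
with inputs sorted by feature id so the result is order-invariant. This
replaces the mafft + fasttree2 step of sequence-database pipelines; no
fidelity to a maximum-likelihood tree is claimed — UniFrac behaviour is
validated against oracles and synthetic truth instead, and on additive
distances NJ provably recovers the generating topology.

`pcoa()` performs Gower double-centering of `-D^2/2` and returns
coordinates for positive eigenvalues only, reporting the count of negative
eigenvalues rather than correcting them.

`permanova()` is the single-factor adonis-style test: total and
within-group sums of squared distances, pseudo-F, `R^2 =
SS_between/SS_total`, and a permutation p-value. When the number of
distinct label assignments is at most 10,000 it enumerates them exactly
(for two balanced groups of 3 that is 20 assignments, so the smallest
attainable p is 0.05 and a fully separated toy gives exactly p = 2/20);
otherwise it draws 999 permutations by default and reports
`(1 + #{F* >= F}) / (1 + n)`. Degenerate cases follow fixed conventions:
all-zero distances give `R^2 = 0, p = 1`; perfect separation gives an
infinite pseudo-F with p still from permutations. Raw permutation p-values
are reported; any multiplicity adjustment across metrics or comparisons is
left to the caller. Multi-factor models are out of scope.

## Mock-community evaluation

Under equal-mass gDNA pooling the molar genome amount is inversely
proportional to genome size and each genome contributes amplicons in
proportion to its rRNA copy number, so the expected read fraction of taxon
*i* is `(c_i/s_i) / sum_j (c_j/s_j)`. This amplicon-level basis is the
default because sequencing observes amplicons, not cells; `basis =
"genome"` gives the molar-genome alternative. The shipped 8-member
reference table (genome sizes, copy numbers, and the vendor's stated
16S-level fractions) reproduces the vendor fractions from first principles
— Bacillus 0.174, Staphylococcus 0.155 — which is also the package's
fidelity anchor to published mock-community expectations.

`compare_observed_expected()` summarises replicates with the sample
standard deviation (n-1) and `log2(observed/expected)` per taxon. Note that
a planted amplification bias `b` on one taxon appears in `log2_bias` as
`log2(b)` *minus the renormalization constant* `log2(sum p_j b_j)`;
centering the biased taxon's log-ratio on the unbiased taxa's mean removes
that constant exactly, which is how the acceptance script recovers
`log2(1.6)` from a 1.6-fold planted bias.

## The synthetic-data generator

The generator defines the study conditions; it is deliberately simple and
fully seeded.

* **Scaffold.** One fixed operon template (16S 1,542 bp, ITS 400 bp, 23S
  prefix 900 bp) shipped as plain FASTA, with the default designs' primer
  sites embedded exactly at realistic offsets (the long insert is 2,454 bp,
  i.e. a ~2.5 kb amplicon). Divergence is never applied inside primer
  footprints unless mismatch injection is the point of the experiment.
* **Genomes.** `generate_genome()` plants `n_operons` copies into random
  background on random strands: taxon-level divergence (default 10%) is
  drawn under `taxon_seed`, so two specs sharing `taxon_seed` are strains
  of one species; strain-level divergence defaults to ITS-only (2%),
  reflecting where ribotypes actually differ; intra-genome copy variants
  (ITS 2%, 16S 0.5%) are assigned round-robin. Non-contiguous architecture
  inserts a gene-sized spacer between 16S and ITS. Truth annotations cover
  every part and serialize to GFF3.
* **Communities and reads.** Two cohorts with fold-change effects applied
  to a base composition and renormalized, optional Dirichlet
  overdispersion, and reads drawn taxon-by-proportion, copy-uniform,
  sequence-exact with optional iid substitutions (no indels — this keeps
  exact dereplication meaningful). Taxa with no amplifiable copy under a
  design are omitted and logged, and the remaining taxa fill the sample's
  depth, emulating how dropout actually manifests: the sequencer still
  returns full depth. Per-read provenance (genome, operon copy) is
  recorded.

What the generator does **not** emulate: platform error profiles (it has no
indels or quality structure), chimeras, length variation between taxa (all
taxa share the scaffold's part lengths, so equal-length inserts are the
norm rather than the exception), PCR saturation, and extraction/lysis bias.
Tests passing on this truth therefore validate the analysis logic, not
wet-lab robustness.

## Benchmark study conditions

The fixed cohort benchmark (`benchmark_community()`) uses 24 samples (12
per cohort) at depth 5,000 with error rate 0, six taxa with a skewed base
composition, and a three-fold effect on two taxa. The structure is chosen
so that every metric family carries signal: a 5% taxon's fold drives the
abundance-aware metrics, while a 0.11% taxon with 12 operon copies carrying
12 ITS variants sits near the per-sample detection limit (about 0.45
expected reads per variant), so its fold flips variant presence and drives
the presence/absence metrics. Folding a highly abundant taxon instead would
renormalize the rare taxon's contrast away — a compositional effect worth
remembering when designing such experiments. This configuration was fixed
by power analysis of the design and verified stable across unrelated seeds
before freezing.

Other problem sizes used by the tests and the acceptance script: 10,000
random instances for the primer-scan oracle; 500 random tree pairs (3-8
leaves) for the UniFrac oracle; 2,000 null simulations at 999 permutations
for type-I error calibration; depth 1e5 for bias recovery. The type-I
check accepts rejection rates in [0.04, 0.06] at alpha = 0.05, i.e. about
two binomial standard errors around the exact level of the permutation
test.

## A worked example

```{r example, eval = FALSE}
designs <- default_designs()
bench <- benchmark_community()
truth <- generate_community(names(bench$base), n_per_cohort = 12,
                            base = bench$base, fold = bench$fold, seed = 1)
reads <- generate_reads(bench$genomes, truth, designs$STRAINID,
                        depth = 5000, seed = 2)
ft <- dereplicate_asvs(reads$reads)
tree <- build_tree(ft$sequences)
permanova_table(ft, truth$cohort, tree = tree, seed = 3)
```

## Known limitations

* The long design's reverse primer is a placeholder, not the commercial
  sequence; results depending on its exact thermodynamics do not transfer.
* Primer-driven operon census approximates gene boundaries by primer
  footprints.
* Exact dereplication stands in for denoising; error rates above ~1% will
  inflate ASV counts unless `min_total_count` is raised.
* The NJ tree is a distance tree over amplicons, adequate for UniFrac on
  synthetic truth but not a substitute for ML phylogenetics on real data.
* Published cohort statistics that depend on deposited raw reads and
  proprietary reference databases are outside what the synthetic pipeline
  can or should reproduce; the package reproduces the *logic* (bias
  evaluation, ASV concordance, design dropout, metric behaviour) on
  generated truth instead.
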