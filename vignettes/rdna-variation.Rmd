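---
title: "Quantifying intragenomic rDNA variation from long-read amplicons"
author: "rdnavar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intragenomic rDNA variation from long-read amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdnavar)
```

## The problem

Nuclear ribosomal DNA occurs in tandem arrays of dozens to hundreds of
copies per genome. Concerted evolution normally homogenises these
copies, but variants regularly escape it, so a single fungal strain can
carry one or two dominant rDNA haplotypes plus a halo of divergent
minor copies. Single-molecule circular-consensus (CCS) amplicon
sequencing reads every copy, which is both an opportunity — the first
direct view of intragenomic variation in barcoding markers — and a
hazard: minor variants can sit far outside the species' usual range
and mislead identification. rdnavar implements the complete desk-side
workflow for this setting, for amplicons spanning the full ITS region
(ITS1–5.8S–ITS2) together with the D1–D2 domains of the nuclear LSU:

1. CCS-level quality filtering (subread count and read quality),
2. dual-barcode demultiplexing with mismatch tolerance,
3. primer-anchored cleaving of each amplicon into its ITS and LSU barcodes,
4. greedy identity clustering with per-cluster consensus calling,
5. p-distance divergence summaries per strain and species,
6. minimum spanning haplotype networks, and
7. distance-based identification against a Sanger reference panel.

A synthetic data generator emulates the whole measurement process with
known ground truth, so every stage is testable without touching real
sequencing archives.

## Pipeline model and parameters

Defaults (all in `pipeline_config()`) follow the protocol the package
models. Reads need at least 5 subreads and predicted quality ≥ 0.99;
both bounds are inclusive. Sample barcodes are matched by Hamming
comparison over the terminal window of barcode length, allowing at
most 3 mismatches *per barcode* (not summed over the pair) — Hamming
rather than edit distance because residual CCS indel errors are rare
after the quality filter, and it keeps an exact oracle trivial.
Demultiplexing tests both orientations and both ends; reads matching
more than one (sample, orientation) combination are conservatively
discarded as ambiguous rather than best-hit assigned, which suppresses
tag-switching artefacts. Amplicons of 1000–2000 bp (inclusive; applied
after barcode trimming) are kept.

Cleaving is anchored on the ITS4 priming site. ITS4 primes the reverse
strand, so the forward-strand motif searched is the primer's reverse
complement; the minimum-mismatch offset wins, ties leftmost, with the
same 3-mismatch budget. The matched 20-bp window is excluded from both
parts: it is invariant by construction and carries no signal. Whether
that window belongs to the ITS barcode is a convention; excising it is
this package's choice. Reads where the cut leaves an empty part are
discarded for that region only.

Clustering reproduces the documented greedy-incremental behaviour of
identity clustering tools: sequences sorted longest first (ties by
id), each joining the first cluster whose representative it matches at
≥ 97% identity, else founding a new cluster. Identity is matched
columns over the shorter sequence's length (the same tools'
convention; alignment-length denominator available as a switch). Each
cluster is then star-aligned against its representative and a
majority-rule consensus called per column, ties broken toward the
representative, gap-majority columns deleted. A star alignment
replaces a progressive multiple aligner deliberately: within a cluster
all members are ≥ 97% identical to the representative, where the two
give the same consensus, and the star construction is exactly
reproducible against a pairwise-alignment oracle.

All pairwise comparisons use one alignment model: global alignment
with unit mismatch and unit gap costs, minimising cost and, among
cost-optimal alignments, maximising matched columns. The secondary
criterion pins down the match/mismatch/gap column counts uniquely, so
identity and p-distance are well defined even when several unit-cost
optima exist. The implementation runs inside a diagonal band that
doubles until the banded optimum is provably the full-matrix optimum
(an alignment of cost *c* deviates at most *(c − |n−m|)/2* from the
diagonal corridor), so results are exact, not approximate. One
consequence worth knowing: above roughly 10% divergence the aligner
occasionally trades two mismatches for a gap pair at equal cost,
so measured p-distances sit slightly below the planted substitution
fraction. At the divergences that matter here (≤ 9% within strains)
the effect is negligible, and it can only lower, never raise, a
distance.

p-distance is the proportion of mismatched columns among gap-free
columns (pairwise deletion; complete deletion available for jointly
aligned sets). The divergence report computes four summaries:
intragenomic (consensus pairs within a strain), Sanger–PacBio
discrepancy (each consensus against the strain's Sanger sequence),
intraspecific by Sanger (between-strain Sanger pairs within a
species), and intraspecific by PacBio. The last uses *all* consensus
sequences of a species' strains, between-strain pairs only: minor
variants must contribute, otherwise the PacBio intraspecific values
could never exceed the Sanger ones the way divergent minors make them,
and within-strain pairs are already counted by the intragenomic
statistic. Empty pair sets render as `-`.

Haplotype networks collapse jointly aligned consensus plus Sanger
sequences into haplotypes (identical aligned rows; alignment again by
star against the most frequent sequence) and connect them by the
minimum spanning network at ε = 0: distance classes processed in
ascending order, an edge admitted iff its endpoints lie in different
components *as frozen at the start of its class* — exactly the union
of all minimum spanning trees, which the tests verify against
exhaustive spanning-tree enumeration. Columns containing a gap are
unscored in the mutational distance. For ε > 0 each pair's admission
threshold is relaxed by ε distance units beyond the class at which its
components first connect; this grows monotonically with ε and is
shipped as a documented extension, with ε = 0 the contract-tested
setting.

Identification assigns each consensus to the species of its nearest
reference by p-distance (ties: smaller mean distance to the species'
references, then lexicographic), and flags it `outlier` when that
species differs from the strain's putative origin. The combined
two-region mode weights per-region distances by reference region
length, the concatenation-equivalent rule. Distance-based
nearest-reference assignment stands in for phylogenetic placement: the
underlying criterion — does a sequence fall with its own species'
references — is a proximity statement, and the package's scope
deliberately excludes ML/Bayesian tree estimation. A neighbor-joining
tree (`nj_tree()`, via ape) is provided for visual QC only.

## What the simulator emulates — and what it does not

`simulate_dataset()` draws one ancestral cassette (ITS ≈ 620 bp,
invariant ITS4 site, LSU ≈ 880 bp), derives each species at 10%
divergence from it (pairwise species distances ≈ 19%), each strain's
major haplotype at 0.2% from its species cassette (intraspecific
Sanger distances of a few per mille), and 0–3 minor haplotypes per
strain. Dominant read counts are uniform on [99, 427] and minor counts
on [1, 14], matching the observed cluster-size ranges; subread depths
are 5 + Poisson with mean 33 (depth ≥ 5, mean ≈ 33); errors are
i.i.d. substitutions at 0.2% per base (read accuracy ≥ 99%), the
simplest model consistent with CCS filtering; reads carry dual 16-bp
barcodes (pool-wide pairwise Hamming distance ≥ 8) and random
orientation.

Minor-variant divergences are drawn from the grid
{0.01, 0.045, 0.06, 0.075, 0.09}, spanning the observed intragenomic
range. The grid deliberately avoids the 3% clustering radius: a
variant closer than `1 − identity` to the dominant haplotype is
necessarily absorbed into the dominant cluster (every read of it
matches the dominant representative at ≥ 97%), so its cluster
membership at the boundary is not a property of the data but of
floating noise. With the grid, the truth-side prediction
(`expected_clusters()`: single-linkage merging of true haplotypes at
the clustering radius, read counts summed, consensus by plain
per-column majority over the realised reads) is unambiguous, and the
pipeline's output can be required to match it exactly. The 0.01 level
keeps sub-radius variants in the data precisely so that tests confirm
they are absorbed and masked in the consensus.

Substitution-only mutation is the default so that all length
arithmetic in truth tables is exact; an error model with indels would
mirror CCS residual errors more closely but would buy realism at the
cost of exact oracles. Not modelled: chimeras and tag switching
(available as a stress knob at zero by default), per-base quality
strings beyond the single rq scalar, PCR-polymerase-specific error
spectra, length variation among rDNA copies, and genuine phylogenetic
structure among species (a star phylogeny from one ancestor). Passing
tests therefore demonstrate the pipeline's correctness under a clean
multi-copy model, not robustness to chimeric or structurally variable
real-world libraries.

The generator treats read counts as proportional to copy number; the
actual mapping between copy number and CCS yield in real libraries is
unknown, so simulated "copy proportions" are a modelling assumption,
not an empirical claim.

## Numerical and degenerate-input choices

Ties in consensus calling go to the cluster representative; ties in
major-variant selection to the lowest cluster index; ties in primer
location to the leftmost offset; classification ties as above. Cluster
ids are `<sample>-C<k>` numbered by decreasing size. Sorting uses
byte-order (`method = "radix"`), and reruns with identical inputs and
seed produce byte-identical TSV output. Zero-read inputs propagate as
empty outputs with a warning, not errors; empty pair sets give `NA`
(`-` in tables); a cluster of one read is its own alignment and
consensus. All coordinates in outputs are 0-based half-open.

## Problem sizes used in the checks

The end-to-end validation runs the generator at study scale — 9
species × 2 strains, ≈ 4,600–5,000 reads of ≈ 1.55 kb — through the
whole pipeline (about a minute), and checks: 100% demultiplexing
accuracy, exact recovery of the dominant consensus per strain and
region, cluster read-count structure equal to the truth-side
prediction, intragenomic means within ±0.005 of truth, and ≥ 95%
concordant major-variant classification. Oracle checks run 500 random
alignment pairs against a brute-force DP and 200 random ≤ 7-node
instances against exhaustive spanning-tree enumeration. Smaller
configurations of the same generator drive the per-module tests.

## Known limitations

Greedy clustering is order-dependent by design (longest first, ties by
id), as in the tools it mirrors; a variant exactly at the identity
threshold can flip cluster membership with a single sequencing error,
which is why the simulator's divergence grid avoids that boundary.
The aligner's equal-cost gap trading slightly deflates distances above
~10% divergence (see above). Star alignment is adequate at
within-cluster identity but is not a general-purpose multiple aligner;
`p_distance_matrix(method = "complete")` inherits that caveat.
Classification reports no support values — the margin to the
second-best species is the only confidence proxy.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_dataset(n_species = 3, strains_per_species = 2, seed = 1,
                        its_len = 300, lsu_len = 400,
                        dominant_range = c(30L, 60L))
res <- run_pipeline(sim$reads, sim$barcode_map, outdir = "pipeline_out",
                    references = sim$references,
                    config = pipeline_config(min_len = 500, max_len = 900))
res
res$divergence$ITS
network_report(res$networks[[1]])$haplotypes
```
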