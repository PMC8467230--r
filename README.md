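# rdnavar

Intragenomic ribosomal DNA variation from long-read amplicons.

Nuclear rDNA is multi-copy, and variants that escape concerted
evolution persist as divergent minor copies inside a single genome.
Long-read circular-consensus (CCS) amplicon sequencing of the fungal
barcoding cassette — the full ITS region (ITS1–5.8S–ITS2) together
with the D1–D2 domains of the nuclear LSU — reads every copy, which
makes intragenomic variation visible but also lets divergent minor
variants masquerade as other species. `rdnavar` is for mycologists and
barcoding practitioners who want to quantify that variation and still
identify species reliably from such data.

## What it computes

Given tagged CCS-level reads, a barcode map and (optionally) a Sanger
reference panel, the pipeline:

* filters reads on CCS metadata (subreads ≥ 5, read quality ≥ 0.99),
* demultiplexes on dual terminal barcodes (Hamming, ≤ 3 mismatches per
  barcode, both orientations; ambiguous hits discarded),
* keeps amplicons of 1000–2000 bp and cleaves each at the ITS4
  priming site into ITS and LSU barcodes,
* clusters each sample/region at 97% identity (greedy, longest-first;
  identity = matched columns / shorter length under a unit-cost global
  alignment) and calls a majority-rule consensus per cluster,
* reports the four p-distance summaries per strain and species —
  intragenomic `mean p(cᵢ, cⱼ)` over consensus pairs within a strain,
  Sanger–PacBio discrepancy, intraspecific by Sanger, intraspecific by
  PacBio (between-strain pairs over all consensuses),
* builds per-species minimum spanning haplotype networks (ε = 0: the
  union of all minimum spanning trees of the mutational-distance
  graph), and
* classifies every consensus against the reference panel by nearest
  p-distance, flagging sequences assigned outside their strain's
  species as outliers. The consensus with the most reads — the major
  variant — is the recommended basis for identification.

A synthetic generator (`simulate_dataset()`) emulates multi-copy rDNA
amplicon sequencing with known truth: per-strain dominant haplotypes
(99–427 reads) plus minor variants (1–14 reads) at divergences up to
9%, 0.2% residual error, subread depth ≈ 33, dual barcodes, random
orientation. It drives the whole test suite, so no external data are
needed.

## Worked example

```r
library(rdnavar)
sim <- simulate_dataset(n_species = 3, strains_per_species = 2, seed = 1,
                        its_len = 300, lsu_len = 400,
                        dominant_range = c(30L, 60L))
res <- run_pipeline(sim$reads, sim$barcode_map, outdir = "pipeline_out",
                    references = sim$references,
                    config = pipeline_config(min_len = 500, max_len = 900))
res
#> rDNA amplicon pipeline run
#>   input reads      : 338
#>   ccs_filter       : kept=338, low_quality=0
#>   demultiplex      : assigned=338, unassigned=0, ambiguous=0
#>   length_filter    : kept=338, length=0
#>   consensus records: 30 across 6 samples
#>   major-variant classification: 12/12 concordant
```

Every read passed the filters and was demultiplexed; the six strains
yielded 30 clusters across ITS and LSU, and the max-read consensus of
every strain classified to its own species. The divergence table
mirrors the published layout (`-` marks empty pair sets):

```r
res$divergence$ITS
#>    species strain intragenomic sanger_pacbio intraspecific_sanger intraspecific_pacbio
#>  Species01 MY0101         0.08          0.04                    0               0.0796
#>  Species01 MY0102       0.0866         0.046                    0               0.0796
#>  Species02 MY0201            -             0                    0               0.0235
#>  Species02 MY0202        0.047        0.0235                    0               0.0235
#>  ...
```

Strain MY0101 carries minor variants at ≈ 8% mean distance from its
other copies — far above the 0–0.3% separating strains of the same
species — while MY0201 shows a single variant identical to its Sanger
sequence. The haplotype network table shows the dominant haplotype
shared between Sanger and PacBio sequences and a halo of
low-frequency PacBio-only variants:

```r
network_report(res$networks[["Species01.ITS"]])$haplotypes
#>   haplotype frequency                                                  sequences       class
#> 1     Hap 1         4 MY0101 (SAN); MY0102 (SAN); MY0101-C1 (57); MY0102-C1 (38)        both
#> 2     Hap 2         1                                              MY0101-C2 (1) pacbio_only
#> 3     Hap 3         1                                              MY0102-C2 (6) pacbio_only
#> ...
```

A thin CLI wrapper ships at `inst/scripts/rdnavar`
(`rdnavar simulate | run | classify`).

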