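# phyloBaits

Design a targeted-enrichment bait kit from multi-species transcriptome
assemblies, and quality-control the loci that come back from capture
sequencing — the two computational arms of building a phylogenomic
toolkit for a plant family, plus a synthetic-data generator that makes
every stage testable against ground truth.

**Who it is for.** Systematists building a hybridization bait kit for a
non-model clade from a handful of transcriptomes, and anyone
post-processing target-capture assemblies (e.g. HybPiper output) into
paralog-screened, partitioned supermatrices and gene-tree sets.

## What it computes

**Design arm** — from per-species contig FASTA to a bait kit:

1. Six-frame ORF extraction and translation (complete ORFs, >= 100 aa).
2. Greedy identity clustering at 99/97/95/90% to collapse alleles and
   isoforms.
3. A within-species "self-search": any protein with a non-self hit at
   >= 40% identity and >= 0.5 coverage is discarded, keeping only
   low-copy genes.
4. Reciprocal-best-hit orthology against focal taxa. All similarity
   search is exhaustive optimal pairwise alignment (Gotoh, affine gaps,
   free end gaps, BLOSUM62 11/1) with percent identity defined as
   `matches / min(len)` throughout.
5. Per-group alignment, 50%-gap column trimming, exhaustive Fitch
   parsimony over all unrooted topologies, and congruence against a
   reference topology (Robinson–Foulds distance 0 to a co-optimal
   tree).
6. Selection filters: identity below the clustering cutoff, < 5% length
   variation, >= 300 bp, closest species pairs > 75% and furthest
   > 70% identity (> 80% for loci over 1,500 bp), pairwise-identity
   variance <= 130.
7. Degenerate bait tiling: every member species' CDS variant is tiled
   with 120-bp baits at 40-bp spacing (3x coverage) plus an
   end-anchored bait; exports as FASTA/BED with kit summaries.

**QC arm** — from capture recovery tables, alignments and gene trees:

- the 75/75 rule (>= 75% of target length in >= 75% of samples),
  threshold sweeps and shared-locus Venn logic between clades;
- gene-tree paralog screening: a locus whose main/alternative copies
  split into separate clades is dropped entirely;
- parsimony-informative-site counts, low-support branch collapsing,
  outgroup rooting, per-branch gene-tree concordance;
- supermatrix concatenation with gap-filled missing samples and
  `DNA, locus = start-end` partition lines.

**Synthetic data** — `simulateTranscriptomes()` evolves open CDS along
a 5-taxon reference topology (one clade accelerated 2x) with
within-species duplicates, splice isoforms and UTRs;
`simulateRecovery()` and `simulateParalogGeneTrees()` generate capture
outcomes and planted paralog structure, all with truth tables.

## Worked example

```r
library(phyloBaits)

cfg <- simConfig(nGenes = 20, seed = 42)
sim <- simulateTranscriptomes(cfg)
res <- runBaitDesign(sim$transcripts, defaultReferenceTopology(),
                     focalTaxa = c("Monodora", "Marsypopetalum"))
res$summary[c("n_unique_regions", "n_variant_sequences",
              "footprint_bp", "n_baits")]
#> $n_unique_regions
#> [1] 18
#> $n_variant_sequences
#> [1] 87
#> $footprint_bp
#> [1] 26571
#> $n_baits
#> [1] 3034

orthologGroupTruth(res$groups, sim$truth)$recallSingleCopy
#> [1] 1
```

Of 20 simulated genes, 18 ortholog groups survive congruence and the
selection filters; their 87 species variants (a degenerate kit:
several variants per exon) tile into 3,034 baits over a 26,571-bp
capture footprint, and every true single-copy gene was recovered as a
group. The QC arm in the same session:

```r
rm <- simulateRecovery(100, 12, seed = 1)
length(selectLoci(rm))          # loci passing the 75/75 rule
#> [1] 88
thresholdSweep(rm)
#>  >=0% >=25% >=50% >=75% >=95%
#>    99    99    99    88     0
```

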