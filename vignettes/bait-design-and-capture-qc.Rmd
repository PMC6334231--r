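---
title: "Designing a transcriptome-based bait kit and quality-controlling captured loci"
author: "phyloBaits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing a transcriptome-based bait kit and quality-controlling captured loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloBaits)
```

## The problem

Targeted enrichment ("hybrid capture") reduces a genome to a few hundred
pre-selected nuclear loci before sequencing: biotinylated 120-bp baits
hybridize to their targets in solution, everything else is washed away.
The approach is attractive for phylogenetics of non-model plant groups
because a single bait kit, designed once from a handful of
transcriptomes, can resolve relationships from the family level down to
species complexes. Two computational problems stand between a pile of
transcriptome assemblies and a usable kit:

1. **Design**: find exonic regions that are single-copy, orthologous
   across the sampled species, long enough to tile baits over,
   divergent enough to be informative, and phylogenetically
   well-behaved — then tile degenerate baits across each species'
   variant of every region.
2. **Quality control**: after capture and assembly, decide which loci
   were recovered well enough to trust, detect paralogous loci from
   their gene trees, and assemble the survivors into per-locus
   alignments and a partitioned supermatrix.

phyloBaits implements both arms against a synthetic-data generator that
produces transcriptomes with known gene content, so every stage can be
tested against ground truth without touching real sequencing data.

## The design arm

### Similarity search

All sequence comparison goes through one primitive: exhaustive optimal
pairwise alignment (Gotoh's algorithm) with affine gap costs
(`open + k * ext` for a gap of k residues) and free end gaps, under
BLOSUM62 with gap open 11 / extension 1 — the classic protein-search
scoring. A seeded heuristic search would be faster on genome-scale
inputs, but desk-scale protein sets (a few hundred to a few thousand
per species) make the exact search tractable, and it buys two things a
heuristic cannot: determinism (no seed-dependent hit lists) and a
trivially checkable contract (the test suite re-derives scores with an
independent full-matrix dynamic program). Where a heuristic search
would rank hits by E-value, thresholds here are on score, percent
identity, and coverage.

Percent identity is defined **once**, everywhere, as
`matches / min(length a, length b) * 100` — the shorter-sequence
convention used by greedy clustering tools. Mixed conventions are a
classic source of silent threshold drift between pipeline stages, so a
single auditable definition is used throughout clustering, screening
and the selection filters. Since co-optimal alignments can disagree in
their match counts, the aligner canonicalises operand order internally,
which makes every reported statistic exactly symmetric under swapping.

### From contigs to candidate loci

- `extractOrfs()` scans all six frames for ATG..stop open reading
  frames, keeping the longest ORF per (strand, frame, stop codon).
  Collapsing nested ATGs this way mirrors standard transcriptome ORF
  callers; returning every nested start would multiply near-identical
  proteins roughly tenfold with no extra information. The default
  length floor is 100 residues, the conventional minimum for
  transcriptome ORF calling; only complete ORFs (start and stop
  present) enter the design arm.
- `clusterProteins()` reduces allelic and splice-isoform redundancy by
  greedy incremental clustering: proteins sorted by decreasing length
  found or join clusters by identity to the representative. The sweep
  runs at 99, 97, 95 and 90 percent identity; all four sets continue
  downstream.
- `selfScreen()` discards any protein with a non-self within-species
  hit at >= 40% identity and >= 0.5 coverage of both sequences.
  These defaults approximate default protein-search sensitivity; the
  source narrative gives no thresholds, so both are configurable and
  recorded per protein in an audit table.
- `rbhGroups()` runs the reciprocal-best-hit search with a focal taxon:
  species s contributes protein p to focal protein f's group iff p is
  f's best hit in s and f is p's best hit back. Reciprocity is enforced
  against the focal taxon only (a star topology), matching a design in
  which other taxa are compared *against* the focal species; all-pairs
  reciprocity is available behind `allPairs = TRUE`. The search runs
  once per focal taxon (defaults: one from each subfamily analog) and
  once per clustering cutoff; groups found at several cutoffs keep the
  highest-cutoff version (the most conservative redundancy reduction),
  and identical member sets found via different focal taxa are merged.

### Phylogenetic filtering

Each candidate group is aligned (`progressiveAlign()`: UPGMA guide tree
over pairwise identity distances, then profile-profile merges under the
same scoring scheme), trimmed (`trimGappy()`: drop columns with more
than 50% gaps), and its topology inferred by **exhaustive Fitch
parsimony** (`inferTopology()`): every unrooted topology is scored (15
for five taxa) and all minimum-score topologies returned. For at most
five species, replacing a likelihood tree search with the exact
parsimony optimum makes the congruence decision deterministic and
oracle-checkable; with more than 8 taxa the function refuses rather
than silently approximating. A group is congruent
(`isCongruent()`) when the reference topology restricted to its taxa is
Robinson-Foulds-identical to at least one co-optimal topology —
co-optimal ties get the benefit of the doubt, which matches the
permissive spirit of "congruent with known relationships". The default
reference is the five-species tree
`((Mkilua,(Monodora,Monanthotaxis)),(Marsypopetalum,Sapranthus))`.

`applySelectionFilters()` then applies the numeric rules, in order,
each recorded with its observed value and threshold in a
`FilterReport`:

| rule | meaning | default |
|------|---------|---------|
| divergence | max pairwise identity strictly below the group's clustering cutoff | group cutoff |
| length variation | (max-min)/max CDS length | < 0.05 |
| minimum length | shortest CDS | >= 300 bp |
| closest pairs | identity of phylogenetically closest pairs | > 75% |
| furthest pairs | identity of furthest pairs | > 70% |
| long sequences | closest pairs when max CDS > 1500 bp | > 80% |
| identity variance | sample variance of all pairwise identities | <= 130 |

Design choices worth stating explicitly, because the narrative the
rules come from leaves them open:

- "Phylogenetically closest/furthest" is decided by **nodal
  (edge-count) distance** on the reference topology: the reference
  carries no branch lengths for this judgment. All tied pairs must
  satisfy the threshold (the conservative reading).
- Thresholds printed on mixed scales (0.75 vs 80) are normalised to
  percent once, in `filterParams()`.
- The identity-variance cap is read as the **sample** variance in
  percent-squared units; population variance is a flag.
- Identity rules are strict (`>`) as printed; the length floor is
  inclusive (300 bp passes). Both semantics are configurable.
- Whether the divergence rule uses the group's own cutoff or the most
  stringent one is undocumented in the source narrative; the group's
  own cutoff is used, which is the weaker reading, and the choice is a
  single parameter if a sensitivity analysis is wanted.
- Length variation is measured relative to the maximum; relative-to-min
  or mean would differ only in the third decimal at the 5% cap.

### Bait tiling

Surviving groups become `TargetRegion`s, one per group, with one CDS
variant per member species — a deliberately *degenerate* kit: if an
exon is present in four species, baits are generated for all four
variants to raise capture efficiency across divergent lineages.
`tileBaits()` places 120-bp baits at 40-bp start spacing (3x tiling:
`bait length / step = 3`), with one extra end-anchored bait when the
last regular start misses the 3' end. End-anchoring is our choice — the
tiling rule as published specifies spacing only — and it guarantees
every base is covered at least once while interior bases are covered
exactly three times; both properties are asserted in the test suite,
as is the closed-form bait count
`floor((L-120)/40) + 1 + [(L-120) mod 40 != 0]`.
`kitSummary()` counts unique regions once, so the capture footprint
uses one representative length per region (the longest variant; the
accounting convention is explicit because multiplicities make
"footprint" ambiguous). No GC-content, melting-temperature or
repeat-masking filters are applied: bait synthesis vendors run their
own QC at ordering time, and a pass-through hook is the honest default
when those criteria are undocumented.

## The quality-control arm

`RecoveryMatrix` (a `SummarizedExperiment` of recovered length per
locus x sample, with per-locus target lengths) drives the **75/75
rule**: `selectLoci()` keeps loci with at least 75% of their target
length recovered in at least 75% of samples. Recovery fractions are
capped at 1 — assembly overhang past the target says nothing about
completeness — and both thresholds are inclusive, a documented choice
where the published wording alternates between "75%" and "over 75%".
`thresholdSweep()` tabulates locus counts over length thresholds
(0 meaning any nonzero recovery), and `sharedLocusSets()` computes
per-group 75/75 sets and exact inclusion-exclusion region counts for
up to four groups.

`paralogCladeTest()` screens flagged loci using their gene trees: for
every sample with multiple assembled copies, it asks whether that
sample's tips form a clade on the unrooted tree. Copies that are
alleles or assembly artifacts sit together; real paralogs sort by
duplication event, splitting each sample's copies into separate
clades — in which case the whole locus is dropped rather than risking
a mixed-orthology alignment.

`collapseLowSupport()` contracts internal edges with bootstrap support
**below** the threshold (default 10) into polytomies before
coalescent-summary analysis. The published description of this step
says branches *above* 10 were collapsed, which would delete essentially
every resolved branch and contradicts the cited practice; we implement
below-threshold collapse and expose `invert = TRUE` rather than
silently correcting the text.

`concatenateLoci()` builds the supermatrix: loci ordered
lexicographically (no order is stated anywhere, and lexicographic is
reproducible), missing samples gap-filled, and a partition table
mapping each locus to its 1-based inclusive column range (written as
`DNA, <locus> = <start>-<end>` lines). `countPIS()` counts
parsimony-informative sites (>= 2 states each in >= 2 rows; gaps and N
are not states). `branchConcordance()` reports, per species-tree
bipartition, the fraction of informative gene trees containing the
induced bipartition — a bipartition-support summary, deliberately *not*
a quartet score: gene trees with fewer than two tips on either side of
the branch are excluded from that branch's denominator.

## The synthetic-data generator

`simulateTranscriptomes()` produces per-species transcript FASTA with a
truth table. Its defaults are the study conditions the package is
validated under, not tuning knobs:

- the five-species reference topology above, terminal branches 0.02
  and internal branches 0.015 expected nucleotide substitutions per
  site — chosen so closest-pair protein identities land in the 80-90%
  band the selection filters discriminate in;
- a rate multiplier of 2 on one three-species clade, mirroring the
  long-branch/short-branch subfamily contrast reported for this family
  (and verifiable on the emitted true gene trees);
- 200 genes of 100-700 codons, covering the 300 bp filter floor up to
  multi-kb targets;
- 10% of genes carry a within-species duplicate evolved 0.25
  substitutions/site away — far enough below the clustering cutoffs to
  survive clustering, close enough to trip the 40%-identity low-copy
  screen, which is precisely the failure mode the screen exists for;
- 10% of genes emit a splice isoform (an internal in-frame deletion of
  10-30% of codons), which clustering should absorb;
- UTRs of 30-150 bp of uniform random composition at both ends.

The substitution process is a single-parameter nucleotide model with
stop-codon rejection; indels are codon-length multiples inside the CDS.
This is deliberately minimal: the filters act on identity gradients,
length variation and topology signal, and a richer model (codon bias,
selection, rate variation across sites) would change none of the
decision boundaries being tested. What the simulator does **not**
emulate — assembly fragmentation and chimerism, alignment error from
real indel processes, base-composition heterogeneity, missing-data
structure of degraded specimens — bounds what a green test suite shows:
the pipeline logic is correct on clean inputs with known answers, not
that any particular empirical dataset will behave.

`simulateRecovery()` models capture outcomes as Beta-distributed
recovered fractions (mean 0.85, concentration 25, dropout 5%, with a
lower mean for designated degraded samples, standing in for
herbarium-type material), and `simulateParalogGeneTrees()` plants
either allelic copy pairs (sister tips) or true between-sample paralog
splits (separate main/alt clades) for the clade test to find.

All randomness flows from one integer seed; each internal stage derives
its own stream so stages are individually reproducible, and identical
seed + configuration give byte-identical FASTA.

## Numerical and implementation notes

- Pairwise kernels score in exact 32-bit integer arithmetic (BLOSUM62
  and the gap costs are integers), so scores are platform-exact; the
  profile aligner works on real-valued mean column scores.
- Ties are broken deterministically everywhere: lexicographic id order
  in best-hit maps and cluster founding, canonical operand order in
  pairwise statistics, sorted locus order in concatenation.
- The problem sizes exercised by the tests — 200 simulated genes, five
  species, the 469-locus recovery fixtures, 15-topology exhaustive
  searches — were chosen as the smallest sizes at which every claimed
  property is non-trivially exercised.
- Degenerate inputs are contracts, not surprises: empty FASTA warns and
  returns an empty set, an all-gap trimming result warns, a zero target
  length names its locus, non-monophyletic outgroups are errors, and
  the exhaustive topology search refuses more than 8 taxa.

## Known limitations

- The clustering step approximates greedy identity clustering, not any
  specific tool's short-word prefilters; cluster boundaries can differ
  from CD-HIT's on adversarial inputs.
- Gap-fraction trimming stands in for both entropy-based (BMGE) and
  block-based (GBLOCKS) cleaning; it reproduces the stated 50% gap
  rule and nothing subtler.
- No maximum-likelihood or Bayesian gene-tree inference, no quartet
  scores or local posterior probabilities: topology work is exact
  parsimony (design arm) and bipartition bookkeeping (QC arm) by
  construction.
- The RBH search is exhaustive and exact; it is not intended for
  genome-scale protein universes.

## A worked miniature

```{r mini, eval = FALSE}
cfg <- simConfig(nGenes = 20, seed = 42)
sim <- simulateTranscriptomes(cfg)
res <- runBaitDesign(sim$transcripts, defaultReferenceTopology(),
                     focalTaxa = c("Monodora", "Marsypopetalum"))
res$summary
orthologGroupTruth(res$groups, sim$truth)$recallSingleCopy
```

With 20 genes this runs in well under a minute and recovers every
single-copy gene; the acceptance script
(`scripts/acceptance.R`) runs the same pipeline at the full default
conditions and reports the recall it measures.
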