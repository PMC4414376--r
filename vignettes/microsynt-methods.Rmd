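---
title: "Microsatellite-anchored synteny and comparative statistics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microsatellite-anchored synteny and comparative statistics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microsynt)
```

# Overview

`microsynt` compares two draft genome assemblies of closely related species
without whole-genome alignment. Its anchors are microsatellites (simple
sequence repeats, SSRs): short tandem repeats whose unique flanking sequence
identifies one-to-one orthologous positions even between fragmented draft
assemblies. From the ordered marker map the package builds synteny blocks,
classifies intra- and inter-chromosomal rearrangements, and, independently of
the synteny machinery, computes assembly summary statistics, protein-domain
expansion/contraction statistics, and CpG-depletion-based methylation
predictions. A synthetic-data generator produces assembly pairs with a known
rearrangement history so that every stage can be validated against ground
truth — the package's entire test strategy rests on it.

This vignette explains the models and procedures, the tunable parameters and
their defaults, the numerical choices, and what the synthetic validation does
and does not demonstrate about real data.

# Marker detection

## Perfect tandem repeats

`find_ssrs()` reports every maximal perfect tandem run of a 1–6 bp motif
meeting a per-motif-length minimum unit count. The defaults (12 units for
mononucleotide repeats, 6 for dinucleotide, 5 for tri- through
hexanucleotide) follow the thresholds most SSR surveys use; they are short
enough to give dozens of markers per megabase in AT-rich insect genomes and
long enough that chance runs are rare. Only perfect repeats are scanned:
because homology is decided on the flanks and not on the repeat itself,
imperfect-repeat support would add complexity without adding matching power.

Three conventions matter downstream:

* **Canonical motifs.** Each repeat is named by the lexicographically
  smallest string among all rotations of its motif and of the motif's
  reverse complement (`canonical_motif()`), so the same locus found on
  either strand or in any phase carries one name. Motifs that are themselves
  repetitions of a shorter motif are never reported at the longer period.
* **Whole-unit truncation.** A maximal run is truncated to whole units
  (a 13-base AC run is reported as 6 units). Under reverse complement the
  reported interval can therefore shift by up to one sub-unit phase; the
  motif and unit count are invariant.
* **N exclusion.** Runs never cross an N, and flanks are truncated at the
  nearest N, so gap characters can shorten but never corrupt a marker.

The scan itself is a single linear pass in C++ over the raw byte sequence
(positions where `seq[i] == seq[i+k]`), which keeps a 250 Mb genome scan in
the tens of seconds. The test suite checks the scan against an independent,
position-by-position exhaustive oracle on a thousand random sequences.

## Flanks

Each locus carries up to `flank_len = 200` bp of sequence on each side,
truncated at scaffold ends and at N. Loci with fewer than
`min_flank_total = 60` bp of combined flank are marked unusable: below that,
a flank no longer identifies a unique genomic position at a few-percent
divergence. 200 bp per side is ample for species that diverged on the order
of ten million years while staying inside typical draft-assembly contigs.

# Marker matching

`match_markers()` identifies one-to-one homologous loci by flank similarity:

1. **Candidate generation.** Candidates are restricted to loci with the same
   canonical motif and at least `min_shared_kmers = 5` shared
   strand-canonical 12-mers between their flanks. The k-mer prefilter is
   correctness-neutral at the accepted-identity range (a true pair at ≤ 10%
   divergence shares hundreds of 12-mers) and reduces the alignment work
   from quadratic to near-linear.
2. **Alignment.** Left and right flanks are aligned separately with
   semi-global (free end gap) alignment (match +1, mismatch −1, gap open 2,
   gap extend 1), in the given orientation (left–left, right–right) and the
   reverse-complement orientation (left vs reverse-complemented right).
   Aligning the flanks separately also prevents the aligner from bridging
   across the repeat, which would otherwise manufacture identity out of the
   uninformative repeat tract. Identity is matches over aligned columns,
   pooled over the two flank alignments; the orientation with more total
   matches wins. Orientation is deliberately *not* chosen on identity: a
   four-column spurious perfect overlap must never beat a 400-column
   99.7%-identity alignment.
3. **Acceptance.** A pair is kept only if identity ≥ `min_identity = 0.90`,
   aligned fraction ≥ `min_aligned_fraction = 0.80` of the shorter combined
   flank, and it is the reciprocal best hit for both loci with the
   second-best candidate at least `tie_margin = 0.02` lower in identity.
   Loci with ties inside the margin are dropped entirely — a near-duplicate
   flank is evidence of a recent duplication or repeat, exactly the loci
   that must not anchor an ordering argument.

The reciprocal-best-hit-with-margin rule is the package's uniqueness
criterion; it enforces the injective marker map that block construction
assumes. At 0.5% pairwise flank divergence the defaults recover essentially
all implanted pairs with no false pairs; the matching property tests also
verify ≥ 95% recall and ≥ 99% precision at 2% divergence.

# Synteny blocks and rearrangements

## Chaining

One assembly acts as the reference. Markers are sorted along each reference
scaffold (`build_tracks()`) and chained greedily (`build_blocks()`): a block
extends while the next marker keeps the same partner scaffold, the same
orientation, and a partner coordinate monotone in the direction the
orientation implies (increasing for "+", decreasing for "−"). A discordant
run of length ≤ `max_singleton_ignore = 1` is skipped — isolated loci out of
order, or pointing at a different scaffold, are ignored wherever they occur
— while a run of `min_break_support = 2` or more ends the block. Blocks with
fewer than two markers are discarded. Local marker-order jitter from
near-identical coordinates is absorbed by the same singleton-ignore
mechanism rather than a separate positional-tolerance parameter: a
micro-shuffle manifests as a discordant run of length one and is skipped; a
real breakpoint is supported by at least two consecutive discordant loci.

## Event classification

`classify_rearrangements()` counts *events*, not block boundaries. Within
each reference scaffold:

* Blocks are grouped into maximal runs by partner chromosome. Each run on a
  chromosome other than the scaffold's majority partner chromosome is one
  **inter-chromosomal event** — a translocated segment is counted once even
  though it creates two chromosome-switch boundaries.
* Within same-chromosome, same-partner-scaffold stretches, each maximal run
  of minority orientation is one **intra-chromosomal event** — an inversion
  is counted once although it flips orientation at both of its boundaries.
  An out-of-order coordinate jump between same-orientation neighbours (a
  transposition signal) also counts as one intra event.
* A boundary where only the partner scaffold changes is an assembly break,
  never an event: marker order cannot distinguish draft fragmentation from
  biology, so the conservative reading wins. Blocks whose partner chromosome
  is unknown ("unplaced") are excluded from event calling.

Each event carries breakpoint *intervals*: the gaps between the flanking
markers of the adjacent blocks. A correct call therefore localizes the break
to one inter-marker interval, which is the resolution limit of any
marker-based method; base-pair breakpoint refinement is out of scope.

## Links and placements

Two reference scaffolds are linked (`link_scaffolds()`) when one partner
scaffold carries consecutive homologous loci at both of their ends with no
other block of that partner scaffold in between; conflicting proposals for
one scaffold end are resolved by supporting marker count. An unplaced
reference scaffold receives a putative chromosome (`place_unplaced()`) only
when at least `min_placement_support = 3` consecutive markers tie it into a
gap or end of the partner-scaffold context of chromosome-placed scaffolds.
Three is the smallest count clearly above the explicitly ignored singleton
plus one supporting neighbour; "several consecutive loci" is not otherwise
quantifiable. Placements are annotations; the input chromosome map is never
modified.

# Assembly statistics

`summarize_assembly()` reports total sequence length (non-N bases), total
assembly span (including estimated gaps), scaffold and contig counts, and
N50s. Conventions:

* The minimum-scaffold-length filter is strictly greater-than (a 1,000 bp
  scaffold is excluded by a 1,000 bp threshold), applied before all six
  statistics.
* Scaffold N50 is computed on gapped spans; contig N50 on the N-free contig
  lengths from `split_contigs()`, which cuts at runs of at least
  `min_gap = 10` consecutive N (an NCBI-style spanned-gap heuristic,
  configurable) and retains shorter N runs inside contigs.
* `nstat()` is the general N-statistic: the smallest length L such that
  segments ≥ L jointly cover the requested fraction of the total.

# Protein-domain statistics

Input is a per-species table of Pfam-style domain hits (gene, domain,
protein coordinates, model-region coordinates), one record per gene (longest
transcript only). The statistics follow four rules:

* **Split-hit merging** (`collapse_consecutive()`): two adjacent same-domain
  hits merge when the second resumes the model region where the first left
  off (within `model_tol = 10` model positions) *and* sits within
  `protein_gap = 30` residues on the protein. Model continuity separates a
  split alignment of one domain copy from a genuine tandem repeat (which
  restarts at model position 1); the protein-gap condition keeps distant
  re-hits apart. Both tolerances are configurable.
* **Once-per-gene counting** (`count_domains()`): a domain contributes one
  count per gene regardless of copy number.
* **Fisher margins**: `scan_expansions()` tests each domain's occurrence
  count against the total occurrences (once-per-gene) in each species — an
  occurrence-proportion contrast. P values are reported raw by default,
  matching the convention of reporting each domain's own evidence; a
  `p.adjust` method can be switched on.
* **Repeat comparison** (`compare_repeat_numbers()`): proteins cluster by
  arrangement (the *set* of distinct domains, ignoring order and copy
  number); only arrangements present in both species and occurring at least
  twice in at least one species are analyzed; per domain the (min, max)
  repeat-count range per species is reported, and non-overlapping ranges are
  flagged.

Fisher's exact test at the counts typical for domain tables (tens of
occurrences per domain) is mildly conservative: the realized false-positive
rate of the scan on null simulations is slightly below the nominal
`alpha = 0.05`, which the calibration test accounts for by averaging over
replicate simulations.

# CpG-depletion methylation prediction

Germline-methylated CpGs deaminate to TpG over evolutionary time, so genes
with a history of methylation are depleted of CpG dinucleotides. `cpg_oe()`
computes CpG[O/E] = (#CpG × L) / (#C × #G) on non-N bases; a gene is
predicted methylated when its ratio falls below 1 (`classify_genes()`).

* The default region is the gene body defined as all exons concatenated;
  introns can be analyzed separately (`region = "intron"`), enabling the
  exon-versus-intron comparison via `compare_feature_classes()`. CpG
  dinucleotides spanning an exon-exon junction are not counted — they are
  not genomic dinucleotides.
* An undefined ratio (no C or no G in the region) is reported as NA, never
  silently as 0, and such genes are never predicted methylated.
* CpG is its own reverse complement, so the ratio is strand-invariant and
  the annotation strand is irrelevant.

# The synthetic-data generator

`simulate_assembly_pair()` builds one ancestor genome with implanted SSR
loci and derives two assemblies from it. Its defaults *are* the standard
validation condition used throughout the tests: 10 Mb in 5 chromosomes,
38% GC (AT-rich, as in bee genomes), 40 SSR loci per Mb with at least 500 bp
spacing and a motif-length mix dominated by di- and trinucleotide repeats,
0.5% pairwise flank divergence, and a rearrangement history of 6 inversions
and 4 inter-chromosomal translocations, each spanning 6 implanted markers
with a 3-marker clear buffer around every event.

Design choices worth knowing:

* **Mutations avoid the repeat tracts.** Point mutations and indels never
  land inside implanted SSR intervals, so validation exercises the detection
  and matching thresholds rather than repeat decay. Divergence is
  interpreted pairwise: each branch receives rate μ/2 so that the A-versus-B
  flank mismatch fraction is approximately μ.
* **Non-extending implant boundaries.** The bases immediately flanking an
  implanted run are forced not to extend the repeat's period, so the
  implanted unit count is exactly what a perfect-repeat scan recovers and
  truth intervals are exact.
* **Segment selection by markers.** Rearranged segments are chosen as runs
  of consecutive implanted loci with boundaries at midpoints between loci,
  so no locus straddles a breakpoint and every true breakpoint falls in a
  known inter-marker interval — which is what makes exact breakpoint
  evaluation (`evaluate_events()`) possible.
* **Coordinate truth by construction.** Every operation (segment
  permutation, indels, N-gap insertion, fragmentation) is tracked in
  composable coordinate maps; `unlift_position()` inverts them, and the
  evaluation of matching precision uses this map rather than a fixed truth
  list, so correctly matched *background* repeats (which arise by chance in
  the shared ancestor sequence and are genuinely homologous) are credited
  rather than punished.
* **Fragmentation defaults off.** N-gap insertion and scaffold breaking are
  available (`gaps_per_mb`, `breaks_per_mb`) and tested, but default to
  zero: the rearrangement-recovery property is defined against
  chromosome-scale partner scaffolds, because a segment split across
  scaffold pieces is — correctly — an assembly break, not an event, to the
  classifier.

`simulate_domain_tables()` draws both species' genes from one shared
domain-occurrence distribution, so the null hypothesis of equal proportions
holds exactly; per-domain within-protein repeat counts are conserved between
species under the null (the biological reading: repeat number is conserved
unless selection changed it), which is what makes "no repeat flags on null
data" a well-defined expectation. Implanted effects (`expansion` folds,
`repeat_shift` deltas) are the only violations.

`simulate_methylome()` generates two-class gene sets (depleted ≈ 0.65,
non-depleted ≈ 1.05 by default). Realized CpG[O/E] is steered to the class
target by composition-preserving CG swap moves, so per-gene ratios
concentrate within ~0.02 of the target; with a 2 kb gene the two classes are
cleanly separated by the 1.0 threshold. This sharpness is intentional — the
generator validates the classification machinery, not the biological
mixture; real gene sets show a broad bimodal distribution with genuine
overlap near 1, where accuracy is necessarily lower.

## What synthetic validation shows — and what it does not

The simulations demonstrate that the implementation is *correct*: detection
equals an exhaustive oracle, matching is one-to-one and symmetric with
known error rates under known divergence, implanted histories are recovered
exactly with breakpoints localized to one inter-marker interval, the
expansion scan is calibrated, and the classifier separates classes that are
separable. They do not demonstrate that the default thresholds are optimal
for any particular pair of real genomes: real assemblies have non-uniform
repeat densities, segmental duplications that defeat any uniqueness rule,
gap structures correlated with repeats, and rearrangements whose breakpoints
fall in marker deserts. Real-data conclusions are threshold-dependent, which
is why every threshold is a visible, documented parameter.

# Numerical and degenerate-input conventions

* Coordinates are 0-based half-open everywhere inside the package; 1-based
  inclusive only at the GFF3/BED boundary, following each format's standard.
* IUPAC ambiguity codes other than N are normalized to N on input (they
  cannot anchor repeat or flank matching); any other character is an error.
* Empty inputs degrade explicitly: empty pair lists give empty track lists,
  empty block lists give zero-block summaries with zero coverage; an
  assembly with no scaffold passing the length filter is an error, as is a
  Fisher test with a zero margin.
* All generators are bit-reproducible under a fixed seed; the pipeline
  itself has no hidden randomness, so identical configurations reproduce
  identical outputs.
* Problem sizes in the test suite: the rearrangement-recovery property runs
  the full 10 Mb condition over 20 seeds; unit and property tests use 0.6–2
  Mb genomes, 200–2,000-gene tables, and 1 kb oracle sequences — sizes at
  which every check runs in seconds while still exercising the same code
  paths as a full-genome analysis.

# Known limitations

* Marker-based resolution: rearrangements smaller than the inter-marker
  spacing, and breakpoints in marker-poor regions, are invisible.
* Segmental duplications and recent repeat expansions produce flank ties;
  the tie rule drops such loci, trading recall for precision.
* The event classifier needs partner chromosome assignments to call
  inter-chromosomal events; with a fragmented, unanchored partner assembly
  it will report blocks and links but few events.
* Reference asymmetry: blocks are defined along the reference; swapping
  roles gives a consistent but not identical map (the symmetric run is a
  consistency check, not a guaranteed involution).
* The Fisher scan tests each domain against pooled totals; domains are not
  independent (the margins are shared), which matters only at the tail of
  the null distribution.
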