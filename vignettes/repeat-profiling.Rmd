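---
title: "Comparative repeat profiling from low-pass shotgun reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative repeat profiling from low-pass shotgun reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Repetitive DNA — LTR retrotransposons, DNA transposons, satellites,
rDNA — makes up half or more of many plant genomes, yet it is exactly
the fraction that genome assemblies represent worst. `repeatscape`
implements a survey strategy that sidesteps assembly entirely: sequence
each genome at low coverage (around 0.1×), trim reads to a common
length, and compare all reads against all others. At such coverage two
reads almost never sample the same single-copy locus, so any read pair
passing a stringent similarity rule is, with high probability, evidence
of repetition, and the number of similarity hits a read collects is
proportional to the genomic copy number of the sequence it samples.

The similarity rule is the package default throughout: a pair of reads
is a *hit* when the best local alignment in either orientation reaches
at least 90% identity over at least 55% of the read length (110 nt for
200-nt reads). Hits define a graph whose vertices are reads; connected
groups of frequently overlapping reads are repeat families. Clustering
several species' reads together makes orthologous families fall into
shared clusters, so per-species cluster composition immediately
separates ubiquitous, group-specific and species-specific repeats.

Three quantitative readouts follow:

* **Genome proportion.** Reads are the unit of genome mass: a cluster
  holding x% of one species' reads is estimated to occupy x% of that
  genome. This read-count convention is used for every proportion the
  package reports.
* **Copy number.** Two reads of length $L$ overlap by at least
  $o_{\min}$ columns exactly when their start positions lie within
  $L - o_{\min}$ of each other, a window of $w = 2(L - o_{\min}) + 1$
  positions. A single-copy locus therefore contributes
  $h = N w / G$ expected within-species hits per read ($N$ analyzed
  reads, genome size $G$), and $\hat k = \mathrm{hits} / h$ estimates
  copies per haploid genome. Families are classed low / medium / high
  at the strict bounds 100 and 1000 copies/1C. The window model is
  exact for dispersed elements longer than
  $L + 2(L - o_{\min})$; for shorter or tandem units it is biased, so
  the package validates it by rank and class recovery, never by exact
  $\hat k$.
* **Detection probability.** Reads from a $k$-copy family arrive
  approximately as a Poisson process with mean $ck$ at coverage $c$,
  so $P(\text{detect}) = 1 - e^{-ck}$, with detection defined as at
  least one sampled read. The at-least-two alternative would predict
  roughly 26% where this model predicts 63% at $ck = 1$; only the
  at-least-one reading reproduces the canonical 63–74% (10 copies,
  0.10–0.13×) and >99.9% (100 copies) figures, which is why it is the
  package's definition.

## The alignment engine

All-to-all comparison is a k-mer seeded Smith–Waterman (Rcpp):
candidate pairs share at least one exact canonical 16-mer, which covers
both orientations; candidates are aligned with +1/−2 match/mismatch and
affine gaps costing 3 for the first base and 1 for each additional
base. Identity is matches divided by alignment columns, with gap
columns counted, and the overlap is the column count of the
best-scoring local alignment; among co-optimal alignments the
traceback prefers diagonal steps, maximising matches. Ties between
equal-scoring forward and reverse alignments report forward.

Seeding is an optimisation, not a definition: `find_hits()` has an
`exhaustive` mode aligning every pair, and the test suite asserts the
two return identical hit tables on simulated read sets. At 90%
identity over ≥110 nt an exact shared 16-mer exists in all but
pathological cases (11 mismatches spread to cut every 16-mer), and no
loss is observed on any test input. A score-only pass with a provable
lower bound (the weakest alignment that can still pass the thresholds
scores at least $\lceil 0.9 \cdot 110 \rceil - 11 \cdot 3$) filters
candidates before the traceback pass.

One numerical trap is worth recording: $0.55 \times 200$ is
`110.00000000000001` in floating point, so the overlap threshold is
computed as `ceiling(frac * read_len - 1e-9)`.

## Clustering

The reference partition is connected components of the hit graph.
An optional refinement recursively applies the best greedy-agglomerative
two-way split of a component when that split's modularity exceeds a
gate (default 0.3). Refinement is off by default deliberately: reads
from a long element tile its length, so a family component is close to
a path/ring graph, and a balanced 2-cut of a long path has modularity
approaching 0.5 — with the gate at 0.3, refinement would shred intact
families. It exists for the opposite failure mode, distinct families
bridged by a few chimeric edges, and the tests exercise it on two
cliques joined by one edge. Clusters are numbered `CL1, CL2, ...` by
decreasing size with ties broken by the lexicographically smallest
member read id; the "top cluster" view keeps clusters of at least
0.03% of analyzed reads, the package-wide size threshold default.

Specificity calls use a single threshold `min_frac_specific = 0.9`:
one species holding ≥90% of a cluster's reads makes it
species-specific; otherwise the species each holding ≥10% form the
candidate group, and if they are a proper subset jointly holding ≥90%
the cluster is group-specific, else shared-all. The 0.9 default is the
package's declared choice; it is configurable.

## Annotation

Clusters are annotated by majority vote: each member read takes the
label of its best reference hit (nucleotide local alignment at ≥70%
identity over ≥60 nt, either strand, seeded with 12-mers because
reference entries may be far more diverged than read pairs), and the
cluster takes the winning label when at least 5 reads hit the
reference and the winner holds at least 60% of the votes; otherwise it
is "unclassified repetitive". The vote replaces manual curation and is
validated only by recovery on simulations. Protein domains are found
by six-frame translation and local alignment against a protein
reference under BLOSUM62 (gap open 10, extend 2) with a default score
threshold of 80, far above the null distribution of
composition-matched shuffled reads. Tandem-versus-dispersed calls use
within-read k-mer periodicity: a read votes "tandem" when at least 5
identical 8-mer pairs recur at one modal offset; a cluster needs ≥20
reads and a majority of tandem votes. The rule detects units shorter
than the read length, which is the regime in which the distinction is
observable from single reads at all.

## Phylogenetics

Species trees and repeat-family trees are distance trees: p-distances
excluding gap/N sites, Jukes–Cantor correction
$d = -\tfrac34 \ln(1 - \tfrac43 p)$ (saturation $p \ge 0.75$ is an
error, never silently capped), and NJ or variance-weighted BioNJ
(`ape`). Negative branch lengths are clamped to zero with the deficit
moved to the sister branch, preserving path lengths through the
parent. For family trees at read scale, a full multiple alignment is
replaced by consensus-anchored alignment: every read is locally
aligned to the family consensus, written into consensus coordinates
with insertions dropped, and per-species majority consensuses are
compared. This is a declared substitute for aligner-plus-ML tree
programs, validated by topology recovery on simulations, not claimed
equivalent to them.

## Assembly annotation tracks

An assembled sequence is annotated by mapping each read of each
per-label read database (k-mer seeded, both strands, the same
90%/55% rule applied relative to read length) and counting, per
sliding window (100 nt window, 50 nt step), the reads whose best
footprint overlaps the window — footprint counting, not midpoint
counting, is the declared choice. Intervals are maximal runs of
windows where any track reaches density 2, merged across gaps up to
200 nt, discarded under 150 nt, and labelled by the database with the
highest mean density (ties "ambiguous"). All four parameters are
config-exposed defaults. Families of very low abundance can yield
zero hits and silently vanish from the annotation; the tests assert
this behavior on background-only sequences rather than fight it.

Counting only the best footprint per read has one consequence worth
knowing: on a long tandem array, near-equivalent alignment positions
repeat every unit, and each read's single best position is decided by
the array's unit-level mutation pattern, so reads pile onto the
best-matching stretches and can leave other stretches of the same
array below the density threshold. Boundary-accuracy validation
therefore uses dispersed elements, where the best footprint is
unambiguous; for tandem arrays the tracks locate the array reliably
but fragment its interior, and interval output for them should be
read as presence evidence rather than as precise boundaries.

## The simulator

The generator is first-class, tested code, and its defaults are the
study conditions for every stochastic validation in the package.
Family consensuses evolve along a species tree by symmetric
substitutions at the branch-length rate; genomic copies add
independent per-copy substitutions (`intra_divergence`); dispersed
copies (optionally LTR–internal–LTR structured) insert at uniform
positions, tandem and rDNA-like families as head-to-tail unit arrays;
half of all insertions are reverse-strand. Placement uses the exact
uniform construction (sorted uniform draws over the free space plus
cumulative offsets) rather than rejection sampling — identical in
distribution, never fails — and enforces a minimum inter-insertion gap
of one read length so no single read can bridge two distinct planted
families; chimeras between a family and flanking background still
occur and carry the truth label "junction" when no family covers half
the read. Reads have uniform starts, equiprobable strands and i.i.d.
substitution errors (default 0.5%).

The default six-species configuration mirrors a comparative survey:
two sister pairs, a close third species, a divergent outgroup (leaf
branches 0.008–0.020 expected substitutions/site), twelve families —
four shared LTR lineages of 0.9–1.2 kb units, an rDNA-like tandem
amplified threefold in one species, three satellites distributed as
species-specific, pair-specific and trio-specific markers, a LINE, a
DNA transposon and a pair-specific LTR fragment family — giving
1.2–1.3 Mbp genomes with 17–26% planted repeats, 5,000 reads of
200 nt per species. Branch lengths are kept small enough that
orthologous copies across all six species still exceed the 90%
identity rule (worst-case path ≈ 4% plus 2% intra-family plus 1% read
error), because the analysis, like the survey design it follows,
groups orthologous families into common clusters; species separation
is driven by presence/absence and abundance, not by sequence
divergence beyond the threshold. Separate single-species
configurations calibrate copy-number classing (50/150/500/2,000-copy
families, 3 Mbp, 3,000 reads — sizes chosen so that interior reads of
the 2,000-copy family sit clearly above the 1,000-copy class bound
under the window model) and track annotation (a deep read-source
genome carrying many copies of two dispersed elements, and a separate
small assembly genome carrying one copy of each as the annotation
truth — the read-database-versus-independent-assembly situation the
tracks exist for; annotating the read-source genome itself would let
junction reads drag intervals outward, and putting several copies in
the assembly would dilute best-footprint coverage, so both designs
measure artifacts rather than annotation accuracy).

One consequence of the miniature scale deserves emphasis: 5,000 reads
of 200 nt against a ~1.3 Mbp genome is roughly 0.8× coverage, three
hundred-fold denser than the 0.1× regime the method is designed for.
At 0.8×, single-copy background reads overlap each other by chance
(the expected number of qualifying partners per background read is
about 0.7), so the "fraction of reads with at least one hit" readout
— a clean repetitive-fraction estimate at 0.1× — is inflated by
coincidental overlaps here, and the unclassified-repeat column of the
abundance report inherits that inflation. Cluster-based family
proportions are essentially unaffected (chance overlaps form sparse
components far below the top-cluster threshold), which is why every
quantitative validation in the package is cluster-based. Simulating
true low-pass coverage would need tens-of-Mbp genomes, outside desk
scale.

What the simulator does not emulate — and what passing tests therefore
do not show about real data: indels (substitution-only keeps alignment
oracles exact; an indel mode is deliberately absent), nested and
truncated TE insertions, target-site duplications, platform error
profiles such as homopolymer indels, GC bias, and shared single-copy
orthologs between species (backgrounds are independent random
sequence, so cross-species hits arise only from planted families).
Desk-scale problem sizes (total ~30,000 reads, ~1 M hit-graph edges)
were chosen so the full validation pipeline runs in minutes on one
core; all rates and sizes above are the configuration defaults and are
not tuned per run.

## Degenerate inputs and tie-breaks, collected

* Reads shorter than the target length are discarded, never padded;
  reads with >5% N are excluded from sampling pools; `N` never matches
  anything in alignment.
* Empty FASTA files parse to empty sets; empty sequences and duplicate
  ids are parse errors with the record index.
* GFF3 output is 1-based inclusive, BED 0-based half-open. Internally
  the package uses the 1-based closed IRanges convention of its host
  ecosystem rather than 0-based half-open, converting only at the
  format boundary.
* Cluster numbering ties: smallest member read id. Orientation ties:
  forward. Interval label ties: "ambiguous". Q-matrix ties inside NJ
  are delegated to `ape`'s deterministic implementation.
* One seed governs a simulation end-to-end; identical configs produce
  byte-identical genomes, reads and downstream tables.

## Known limitations

Hit counting is quadratic in family read count, so satellite-rich
genomes dominate runtime; the engine targets up to ~10^5 reads, not
millions. Genome proportions are read-count proportions: length biases
(reads straddling family boundaries link less often) depress estimates
of short-unit dispersed families by a percent or two of their value.
The copy-number model assumes dispersed units longer than about twice
the read length; tandem families violate it and are classed by their
effective, not physical, copy number. Cluster annotation inherits the
reference collection's coverage — families absent from the reference
are "unclassified repetitive" regardless of abundance.
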