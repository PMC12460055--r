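---
title: "Consensus assembly from multiple long-read assemblies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus assembly: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Long-read assemblers are imperfect: different tools (or the same tool on
different read subsets) produce different assemblies of the same bacterial
isolate, with assembler-specific substitution/indel errors and structural
mistakes — overlapping circularisation, missed or duplicated small plasmids,
spurious contigs. Because the errors are largely tool-specific while the
genome is shared, a consensus over many alternative assemblies is more
accurate than any single input. `asmconsensus` automates that consensus:
given a directory of assemblies of one isolate, it produces one sequence per
replicon with the most-supported variant at every locus, with no manual
intervention, while writing every intermediate file so a curator can step in
where wanted.

## The procedure

**Compression.** All input contigs are collapsed into a compacted De Bruijn
graph (cDBG). Nodes are canonical k-mers (the lexicographic minimum of a
k-mer and its reverse complement; k is odd, so no k-mer equals its own
reverse complement). Edges are the (k-1)-overlap adjacencies *observed* in
the input contigs — not every overlap implied by the k-mer set — which keeps
the graph faithful to what the assemblers actually produced. Maximal
non-branching chains are merged into unitigs. Every contig is stored as an
oriented walk through the unitigs with start/end offsets, so
`reconstructContig()` is byte-exact: the graph is a lossless, much smaller
representation of all inputs, and downstream stages compare paths instead of
aligning sequences.

Two representational choices matter. Unitigs are stored in the
lexicographically smaller of their two orientations and numbered by
decreasing length (ties by sequence), so the graph is identical regardless of
input order. And a contig whose sequence is internally periodic (its k-mers
recur) maps onto a small cyclic subgraph walked repeatedly — each canonical
k-mer is stored exactly once, and the path offsets keep reconstruction exact.

**Clustering.** The pairwise distance between two contigs is a
length-weighted multiset Dice distance on unitig content:
`d = 1 - 2S/(La + Lb)`, where each path step contributes its full unitig
length and `S` sums `min(count_a, count_b) * length` over unitig ids.
Identical paths give 0, unitig-disjoint paths give 1. A UPGMA tree built
from these distances is cut at a fixed cutoff, refined, and QC-filtered;
ideally one passing cluster remains per replicon.

A point that is easy to get wrong: this distance is *not* per-base
divergence. A single private substitution replaces a ~2k-base window of the
shared path with a private bubble arm, so a pair of same-replicon contigs
with per-base divergence eps sits at roughly `min(1, 2*k*eps)` — with the
default k = 51, contigs differing by 0.1% have path distances of 0.1-0.4,
while contigs of different replicons sit at exactly 1. The default cutoff is
therefore 0.5, the midpoint between the same-replicon regime and
disjointness, not a small value resembling a sequence divergence threshold.
It is overridable (`cutoff=`) for unusual cases such as highly similar
co-resident plasmids.

Refinement addresses clusters that mix replicons: whenever some assembly
contributes two or more contigs to a cluster, the split into the cluster's
two child subtrees is accepted if it strictly increases
`balance - lambda * tightness` (balance: fraction of contributing assemblies
with exactly one member; tightness: mean intra-cluster distance; child
scores combined as a member-weighted mean; `lambda = 0.5`), recursively. QC
then fails clusters present in fewer than `ceiling(0.25 * n_assemblies)`
assemblies (likely spurious contigs) and clusters at least 90% of whose
member-unitig bases occur in a passing larger cluster (fragments, repeat
elements). Failed clusters keep their members so a user can rescue them with
a manual assignment file, which overrides the automatic clustering entirely.

**Trimming.** Assemblers leave three recognisable artifacts at contig ends,
and each cluster member is checked for all three, in order: whole-sequence
tandem duplication (a small plasmid emitted as two head-to-tail copies —
detected by comparing the two halves, which works for any rotation of the
doubled plasmid), hairpin overlap (a prefix or suffix equal to the reverse
complement of the immediately adjacent region), and circular overlap (the
start of the contig repeated at its end). Detection is seeded by exact
shared words (21 bp) and verified by ungapped end-anchored comparison with a
1% mismatch allowance, so scattered sequence errors in one copy do not hide
the overlap; trimming operates on decompressed sequences rather than graph
paths for the same reason. Defaults: minimum overlap 100 bp, maximum overlap
half the contig. After trimming, contigs whose length deviates from the
cluster median by more than 10% are discarded (the contig closest to the
median always survives). All trim detectors are idempotent on their own
output for non-pathological sequences; a genuinely hairpin-terminated
replicon whose true terminus is itself a perfect inverted repeat could
re-trigger detection, which is one reason linear replicons often need manual
curation.

**Resolution.** Each passing cluster is resolved on a fresh cDBG built from
its trimmed members only (so trimming changes propagate and the graph is
small). *Anchors* are unitigs occurring exactly once in every member path
with consistent relative order and orientation — cyclic order for circular
clusters. Members are first oriented to the first contig by majority anchor
strand; order violations are then repaired by dropping the fewest candidates
(smallest unitig first, assessed with a longest-increasing-subsequence check
per member). Between consecutive anchors every member contributes its
intervening unitig walk; identical walks are grouped and the most common one
is the *bridge* (ties broken by support, then fewest bases, then
lexicographically smallest sequence — biased against spurious insertions).

When no whole-gap walk is convincing — top support below
`bridgeMinFraction = 0.25` of members, which happens when bubbles are dense
enough that every member's walk through a gap is unique — the gap falls back
to a per-edge majority walk: starting at the flanking anchor, repeatedly
take the oriented edge traversed by the most members. This recovers the
site-wise majority in exactly the situation where whole-gap voting carries
no signal, and matches the iterative most-supported-path resolution the
overall method calls for. A cluster is marked unresolved only when that walk
cannot reach the next anchor (e.g. contradictory structures); its graph is
still written for inspection and manual `cleanGraph()` editing. With no
anchors at all, the longest retained contig is returned with a fallback
flag.

A cluster is called circular when every member's path closes on itself.
Contig origins complicate this: a rotated contig's k-mer walk is an *arc*
that lacks the k-1 k-mers spanning its own origin, so closure is recognised
either structurally (the first and last path steps are the two halves of one
unitig split at the origin, tiling it exactly once — an offset condition in
bases, not k-mers) or by a junction witness: the 2(k-1)-base window around
the origin occurs contiguously in another member, matched with short exact
seed words and a small mismatch allowance so private errors near either
origin do not break the test. Circular consensus sequences are rotated to
begin at the largest anchor, making output deterministic and
rotation-invariant.

**Combination.** Resolved sequences are written as a final FASTA (one record
per cluster, longest first, headers
`cluster_<id> length=<n> topology=<circular|linear>`, 70-column wrap) and a
GFA 1.0 file with a self-link marking circular sequences. Every stage also
writes a YAML metrics document (sorted keys, flat scalar values) under
`metrics/`; `aggregateTable()` gathers chosen keys across many runs into one
TSV for cohort-level tracking.

**Subsampling.** To generate more independent input assemblies from one
read set, `subsampleReads()` shuffles reads with a seeded permutation and
assigns each of N subsets a contiguous block starting at evenly spaced base
offsets (`round(i * total/N)`), accumulating to the target
`B = max(minDepth * genomeSize, total/N)` bases. Evenly spaced starts
minimise the maximum pairwise overlap of contiguous windows; when total
depth is at least `N * B` the subsets are disjoint, and a subset never wraps
around for less than one read's worth of shortfall (so it lands within one
read of the target rather than overlapping the first subset). Defaults:
4 subsets, 25-fold minimum depth; the genome size is a required user input,
not estimated.

## Serialization

Graphs are GFA 1.0: `S` lines carry the unitig sequence and an integer depth
tag (`DP:i:`), `L` lines an explicit `(k-1)M` overlap CIGAR, `P` lines the
contig paths with offsets and source assembly in tags (`SO:i:`, `EO:i:`,
`AS:Z:`), and the header carries k (`KM:i:`), which also identifies files
written by this package. Reading back a written graph restores it exactly.

## The synthetic-fixture generator

All tests and the acceptance script run on synthetic data generated by the
package itself. `makeGenome()` draws i.i.d. bases at a chosen GC content
(default: a 50 kb circular chromosome plus a 5 kb circular plasmid at
GC 0.5), optionally with one exact implanted repeat to exercise anchor
exclusion. `perturbAssembly()` emulates the documented failure modes of real
assemblers — random rotation of circular replicons, point errors at given
rates, dropped or tandem-duplicated plasmids, circular-overlap or
hairpin-overhang ends, fragmentation — and logs every change to a truth
record, so downstream assertions (trim recovery, cluster membership,
site-wise consensus correctness) are exact. `simulateReads()` is
deliberately crude (gamma lengths, uniform starts wrapping circular origins,
uniform 1% substitutions): it feeds the subsampling contract, not assembler
emulation.

The standard study condition used throughout is 8 pseudo-assemblies with
random rotations and 0.1% substitutions, one assembly missing the plasmid
and one with it tandem-duplicated. What passing these tests shows is that
the graph, clustering, trimming and voting machinery is correct under
realistic error *placement*; what it cannot show is robustness to real
assembler pathologies that the generator does not model — systematic
homopolymer errors, chimeric joins, heterogeneous structural variants, or
repeat-induced fragmentation (i.i.d. genomes have no long repeats, and the
per-edge majority walk assumes a gap subgraph without multi-visit repeats).

## Numerical and degenerate-input choices

- Odd k only (no reverse-complement-palindromic k-mers); k >= 11; default 51
  — long enough that chance 50-mer repeats in a 5 Mb genome are rare, short
  enough to tolerate scattered errors.
- Ambiguous bases: contigs are split at non-ACGT characters, sub-contigs
  shorter than k dropped, both logged in the graph metadata.
- UPGMA ties: the pair whose smallest leaf label sorts first (then the other
  label) merges first; averaged distances within 1e-10 are treated as tied,
  since incrementally updated and directly recomputed averages differ by
  float rounding.
- Tree cutting: clusters are maximal subtrees with merge distance <= cutoff
  (node height <= cutoff/2); a cutoff below the smallest merge gives
  singletons, above the root gives one cluster.
- Contig path offsets are measured on the traversal orientation of the
  first/last unitig; reconstruction is the defining invariant.
- All string ordering uses C-locale radix sorting, so output is identical
  across locales.

## Problem sizes

The test-suite and acceptance-script fixtures are sized for a desk-scale
run: 50 kb + 5 kb genomes with 8 inputs for the pipeline checks, up to
200 bp inputs for brute-force graph-oracle comparisons, distance matrices up
to n = 8 for the UPGMA oracle, and 2 Mb read sets for subsampling. The
algorithms are the same at real bacterial scale (5 Mb, 30+ inputs); the
vectorised graph construction handles a few hundred thousand k-mers per
second, so a full-size run is minutes, not hours.

## Known limitations

- The consensus reflects the inputs: an error shared by most inputs is kept,
  and fully fragmented inputs cannot yield a complete consensus.
- Linear replicons resolve through terminal-segment voting, but hairpin
  topology metadata is recorded only as trim detections; true telomere-like
  ends generally need manual curation.
- Structural heterogeneity is collapsed to the most supported configuration;
  characterising it is a job for a structural-variant caller downstream.
- The per-edge majority fallback can fail (cluster unresolved) in gap
  subgraphs where a repeated unitig must be traversed through different
  exits on successive visits.
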