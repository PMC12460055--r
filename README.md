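# asmconsensus

Consensus assembly of bacterial genomes from multiple alternative long-read
assemblies.

Individual long-read assemblers make tool-specific mistakes: substitution
and indel errors, overlapping circularisation, missed or duplicated small
plasmids, spurious contigs. Given several assemblies of the *same* isolate
(different assemblers and/or read subsets), the shared genome can be
separated from the per-tool errors by voting. `asmconsensus` automates that
process for people who assemble bacterial genomes at scale and want
reference-grade sequences without hand curation — while writing every
intermediate file so curation remains possible in hard cases.

## Method at a glance

1. **Compress** — all contigs are collapsed into a lossless compacted De
   Bruijn graph: nodes are canonical k-mers (odd k, default 51), edges the
   observed (k−1)-overlaps, maximal non-branching chains merged into
   unitigs. Each contig is stored as an oriented walk with offsets, so it
   can be reconstructed byte-exactly (`decompress`).
2. **Cluster** — contigs are compared by a length-weighted multiset Dice
   distance on their unitig content, `d = 1 − 2S/(L_a + L_b)` with
   `S = Σ_u min(c_a(u), c_b(u))·len(u)`; a UPGMA tree is cut at a fixed
   distance, refined by a balance/tightness score, and QC-filtered
   (too-few-assemblies, containment), ideally leaving one cluster per
   replicon.
3. **Trim** — per cluster, whole-plasmid tandem duplications, hairpin
   overlaps and circular overlaps (start of a contig repeated at its end)
   are detected with exact word seeds plus a 1% mismatch allowance and
   removed; post-trim length outliers are discarded.
4. **Resolve** — a fresh per-cluster graph is built from the trimmed
   contigs; *anchors* (unitigs occurring exactly once in every member, in
   consistent cyclic order) scaffold the consensus, and between anchors the
   members vote on *bridges*, the most supported intervening walks (with a
   per-edge majority fallback when every member's walk is unique). Circular
   sequences are rotated to the largest anchor.
5. **Combine** — one FASTA record per resolved cluster plus a GFA with
   self-links marking circular replicons; YAML metrics at every step, and a
   `table` command to aggregate metrics across runs.

A read `subsample` stage (seeded shuffle, evenly spaced offsets, target
depth 25×, 4 subsets) produces minimally overlapping read subsets for
generating more independent input assemblies, and a synthetic-fixture
module (`makeGenome`, `perturbAssembly`, `simulateReads`) generates fully
truth-tracked test data so the whole pipeline is testable without any
external datasets.

## Worked example

Build a synthetic isolate (50 kb circular chromosome + 5 kb circular
plasmid), perturb it into four pseudo-assemblies with random rotations and
0.1% substitutions, and run the full pipeline:

```r
library(asmconsensus)

gen <- makeGenome(seed = 1)
asms <- list()
for (i in 1:4)
  asms[[sprintf("asm%02d", i)]] <- perturbAssembly(
    gen, rotation = "random", substitutionRate = 0.001, seed = 100 + i)$seqs

g <- buildUnitigGraph(asms, k = 51)
g
#> UnitigGraph (k=51): 636 unitigs, 97876 bp, 1696 oriented links, 8 contig paths

res <- runFull(asms, "run1", k = 51)
res$clusterSet
#> ClusterSet: 8 contigs, 2 clusters (2 pass, 0 fail)
res$resolved[[1]]
#> ConsensusSeq cluster 1: 50000 bp, circular (resolved), 174 anchors
res$resolved[[2]]
#> ConsensusSeq cluster 2: 5000 bp, circular (resolved), 8 anchors
```

Reading the output: the 220 kb of input contigs compressed into 98 kb of
unitigs (shared sequence stored once); clustering recovered exactly the two
replicons, one contig per assembly; and each cluster resolved to a circular
consensus of exactly the true replicon length. The final assembly is in
`run1/consensus.fasta`:

```
>cluster_1 length=50000 topology=circular
```

with per-stage YAML metrics under `run1/metrics/` — for instance
`resolve_cluster_001.yaml` records 174 anchors, 174 bridges (3 ambiguous,
resolved by majority), topology circular, consensus length 50000. Because
the fixture's errors are private to single assemblies, every site has a
3-or-4-of-4 majority and the consensus here equals the true genome
byte-for-byte (up to rotation) — verify with
`grepl(consensusSeq(res$resolved[[1]]), paste0(truth, truth), fixed = TRUE)`
where `truth <- gen$seqs$chromosome`.

A command-line wrapper with the same stages
(`full`, `subsample`, `compress`, `decompress`, `cluster`, `trim`,
`dotplot`, `resolve`, `clean`, `combine`, `table`, `fixtures`) is installed
under `exec/`:

```sh
$(Rscript -e 'cat(system.file("exec", "asmconsensus", package = "asmconsensus"))') \
  full -i assemblies/ -o run1 --verbose
```

See `vignettes/consensus-assembly.Rmd` for the model, parameter defaults
and design rationale.

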