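Package: asmconsensus
Title: Consensus Assembly from Multiple Long-Read Bacterial Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Combines multiple alternative long-read assemblies of one bacterial
    isolate into a single accurate consensus genome. Input contigs are collapsed
    into a lossless compacted De Bruijn graph, clustered into per-replicon groups
    by graph-path distance with UPGMA and quality-control filters, trimmed of
    circular/hairpin overlaps and tandem plasmid duplications, and resolved into
    one consensus sequence per replicon via single-copy anchors and majority-vote
    bridges. Includes long-read subsampling for generating independent input
    assemblies, GFA 1.0 serialization of all graphs, YAML metrics at every step,
    and a synthetic-fixture generator (genomes, perturbed pseudo-assemblies,
    simulated reads) for fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
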