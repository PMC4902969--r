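Package: SyntenyAnchor
Title: Reference-Assisted Scaffolding, Chromosome Anchoring and Ancestral
    Karyotype Reconstruction from Conserved Synteny
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for anchoring a fragmented genome assembly to chromosomes
    using conserved gene order against two reference genomes. Detects
    homologous synteny blocks from one-to-one orthologs, proposes scaffold
    joins bridged by consecutive reference genes (with skipping of orphaned
    terminal genes), filters joins by dual-reference consensus and chains
    them into super-scaffolds. Assigns scaffolds and super-scaffolds to
    chromosomes via cytogenetic anchor markers with conservative conflict
    detection, builds comparative chromosome maps with inter- and
    intrachromosomal rearrangement counts, and reconstructs ancestral
    macrochromosome compositions on a phylogeny by Fitch parsimony over
    pairwise segment co-location characters. A deterministic synthetic-genome
    simulator with rearrangement event logs provides known-answer truth sets
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
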