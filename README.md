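# SyntenyAnchor

Anchoring a fragmented genome assembly to chromosomes by conserved synteny.

Many genome assemblies — particularly for non-model reptiles — consist of
hundreds of thousands of sequence scaffolds with no chromosomal context,
which makes comparative questions about karyotype evolution unanswerable.
SyntenyAnchor implements a reference-assisted strategy for this situation,
built for the case where a target genome (e.g. an agamid lizard) can be
compared against two well-anchored reference genomes (e.g. chicken and the
green anole) and a modest set of cytogenetically mapped markers (BAC clones
localised by FISH, tied to scaffolds through their end sequences):

1. **Homologous synteny blocks (HSBs).** From one-to-one orthologs, maximal
   runs of genes contiguous in both genomes (`detectHsbs()`); block
   endpoints are the natural probe targets, and candidate marker regions
   are screened with the standard acceptance filters (exon length ≥ 100 bp,
   male/female identity ≥ 97 %).
2. **Super-scaffolding.** Two scaffolds are joined when the mapped terminal
   gene of one and the mapped terminal gene of the other occupy adjacent
   positions in a reference's gene order (`proposeJoins()`). Orphaned
   terminal genes — the sole mapped gene of a scaffold sandwiched between
   the terminals of two other scaffolds, which would otherwise fork the
   chain — are skipped and logged. Joins are kept only when **both**
   references support the same scaffold-end pairing (`consensusJoins()`),
   then chained into super-scaffolds (`chainJoins()`). A super-scaffold's
   size is the sum of its members' sizes, and its name is the hyphenated
   list of member scaffold numbers (e.g. `15-3-1966`).
3. **Anchoring.** Anchor markers assign scaffolds/super-scaffolds to
   chromosomes (`assignUnits()`). Any disagreement among a unit's markers
   voids the assignment and is reported as a potential assembly error —
   never resolved by majority vote. Coverage per chromosome is summarised
   against estimated chromosome sizes (`coverageTable()`), with marker
   positions expressed as Flpter (fractional length from the p terminus).
4. **Comparative maps.** Units ordered along each chromosome by Flpter are
   coloured by their reference homolog (plurality of mapped genes); each
   maximal run of non-dominant homology counts as one interchromosomal
   rearrangement, and order breakpoints against the reference count
   intrachromosomal rearrangements (`interchromosomalEvents()`,
   `intrachromosomalBreakpoints()`).
5. **Ancestral karyotypes.** Species × chromosome × homology-segment
   profiles become pairwise co-location characters (`together` / `apart` /
   `missing`); Fitch parsimony on a rooted species tree with an outgroup-
   anchored root places fusion and fission events on branches, and
   union-find over `together` characters rebuilds each ancestor's
   chromosome composition (`ancestralKaryotypes()`).

A deterministic simulator (`simulateGenomes()`) generates an ancestor gene
order, two references derived by logged inversions / translocations /
fusions / fissions, a fragmented target with ortholog dropout, planted
orphan scaffolds, and anchor markers — with full truth sets, so every stage
has known-answer tests.

## Worked example

```r
library(SyntenyAnchor)
sim <- simulateGenomes(simConfig(nGenes = 300, nChromosomes = 3,
    nScaffolds = 24, dropoutRate = 0.05, markerDensity = 1, seed = 20))
joinsA <- proposeJoins(sim$target, sim$refA, sim$mapA)
joinsB <- proposeJoins(sim$target, sim$refB, sim$mapB)
consensus <- consensusJoins(joinsA, joinsB)
sset <- chainJoins(consensus, sim$scaffolds)
head(superscaffoldSizes(sset, sim$scaffolds), 4)
#>                      name n_members size_bp
#> 1 17-18-19-20-21-22-23-24         8 1350084
#> 2             7-8-9-10-11         5  873661
#> 3                   4-5-6         3  796213
#> 4          12-13-14-15-16         5  545395
head(assignUnits(sset, sim$markers)$assignments, 4)
#>                   unit_id chromosome_id n_markers
#> 1                   1-2-3          chr1         4
#> 2          12-13-14-15-16          chr2         5
#> 3 17-18-19-20-21-22-23-24          chr3         4
#> 4                   4-5-6          chr1         3
```

Here 21 and 20 per-reference join candidates reduce to 19 consensus joins;
the 24 scaffolds chain into a handful of super-scaffolds (names list the
member scaffold numbers, sizes are exact member sums) and the marker-based
assignments recover the simulated truth chromosomes for every unit.

The ancestral-karyotype stage runs on a bundled squamate example (a rooted
eight-taxon tree and a synthetic encoding of published comparative
cytogenetic mapping for seven squamates plus an archosaur outgroup):

```r
tr <- ape::read.tree(syntenyAnchorExample("squamate_tree.nwk"))
pf <- readKaryotypeProfiles(syntenyAnchorExample("squamate_profiles_synthetic.tsv"))
res <- ancestralKaryotypes(tr, pf, outgroup = "archosaur",
    macroSegments = squamateMacroSegments())
res$ancestors[, c("label", "n_macrochromosomes")]
#>                    label n_macrochromosomes
#> 1           Amniote_root                 11
#> 2               Squamata                 10
#> 3 Lacertoidea_Toxicofera                 10
#> 4             Toxicofera                  7
#> 5    Anguimorpha_Iguania                  7
#> 6                Iguania                  6
#> 7           Agamid_Anole                  6
```

## Package layout

- `R/` — S4 classes (`GeneTable`, `OrthologMap`, `SuperScaffoldSet`) and
  the stage functions listed above, one file per stage.
- `inst/extdata/` — the squamate tree and the synthetic profile matrix
  (see `?SyntenyAnchor` for provenance).
- `vignettes/synteny-anchoring.Rmd` — the model, its assumptions, the
  simulator's design and known limitations.
- `tests/testthat/` — unit, property and end-to-end tests with
  brute-force oracles.
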