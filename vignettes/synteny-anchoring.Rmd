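---
title: "Anchoring fragmented genomes by conserved synteny: models and design"
author: "SyntenyAnchor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchoring fragmented genomes by conserved synteny: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SyntenyAnchor)
```

## The problem and the model

A draft genome in hundreds of thousands of scaffolds carries no
chromosomal information. When two related, chromosome-anchored reference
genomes exist, conserved synteny offers a route to chromosomes without
resequencing: a region whose gene content and order is conserved between
the *two references* is very likely also conserved as a unit in the target
lineage, because the references bracket the target phylogenetically.
SyntenyAnchor operationalises that argument in two complementary forms —
homologous synteny blocks, which transfer a single cytogenetic anchor to a
whole conserved block, and super-scaffolding, which concatenates scaffolds
whose junctions are spanned by consecutive reference genes.

Everything works on *gene order*, never on alignment coordinates: a
genome is a set of sequences, each an ordered list of gene placements with
dense ordinal ranks (0..n−1 per sequence, ties on identical start
coordinates broken lexicographically by gene id so results are
reproducible). On disk, tables are 1-based inclusive TSVs in the usual
genomics convention; in memory coordinates are 0-based half-open.

### Ortholog filtering

All synteny reasoning requires one-to-one orthologs. `enforceOneToOne()`
removes every gene involved in any many-to-many relation, together with
all of its pairs. The operation is idempotent and invariant under input
order — ambiguity is never resolved by accident of row ordering, it is
simply discarded.

### Homologous synteny blocks

`detectHsbs()` partitions the mapped genes into maximal runs that are
contiguous in both genomes with monotone (increasing or decreasing)
position in the second. Genes absent from the ortholog map are
*transparent*: they never break a block. This mirrors how database-derived
HSBs tolerate unannotated or unmapped intervening genes, and it is the
same tolerance the super-scaffolding orphan rule exploits. Orientation
handling is a genuine design choice: gene-order tables assembled from
heterogeneous sources often carry unreliable strand, so the default is
orientation-agnostic (`signed = FALSE`); with `signed = TRUE` the relative
strand of every pair in a run must match the run's direction, with unknown
strands tolerated. Block size selection (the "larger blocks first" used
when choosing probe targets) is by bp span on genome 1, exposed separately
from the `minGenes` threshold (default 2) because the two filters answer
different questions. Candidate marker regions around block endpoints are
screened by `filterMarkerRegions()` with inclusive thresholds — length at
least 100 bp and male/female identity at least 97 % — where identity is a
plain column count over an existing alignment (`percentIdentity()`; gap
and N columns count as mismatches). Producing the alignment itself is out
of scope.

### Super-scaffolding

`proposeJoins()` walks each reference chromosome's mapped genes in order.
A join between scaffolds S1 and S2 is proposed when the mapped terminal
gene at an end of S1 and the mapped terminal gene at an end of S2 occupy
adjacent positions in that walk. "Adjacent after transparency" is the
minimal reading of a junction "spanned by a contiguous series of
consecutive genes"; a `minSupportGenes` parameter optionally requires a
longer monotone run at each scaffold end for stricter settings.

The *orphaned terminal gene* problem: if a scaffold's sole mapped gene
sits in the reference between terminal genes of two other scaffolds, it
links in both directions and the chain forks. The resolution is to skip
such genes — the flanking join is proposed with the orphan recorded in
`skipped_orphans` — while the orphan scaffold itself is retained as a
singleton, never deleted and never absorbed into the super-scaffold. (The
alternative, inserting the orphan between the flanks, is defensible; we
keep it out because single-gene evidence cannot orient the scaffold, and
report it in the join's provenance instead.) With skipping disabled the
two competing candidates are emitted flagged as a fork, so nothing is
resolved silently.

`consensusJoins()` keeps a junction only when both references propose the
identical (scaffold, end)–(scaffold, end) pairing. Consensus is on the
pairing, not on the bridge genes: the two references need not share gene
content at the junction, only the implied adjacency. `chainJoins()` then
treats scaffold ends as graph nodes. Conservatism is the rule at every
ambiguity: an end claimed by two junctions loses *all* its junctions (no
scoring, no voting); any cycle — which cannot be a correct linear
chromosome fragment — is broken at its weakest junction (smallest total
bridge-gene support, ties by lexicographic junction key, so the result is
deterministic). What remains are simple paths: super-scaffolds with
orientations propagated along the path, named by their member scaffold
numbers with the smaller terminal number first (a path read backwards is
the same object). Sizes are exact sums of member lengths — no gap model.

### Anchoring and conflicts

`assignUnits()` is deliberately strict: a unit (super-scaffold or
singleton scaffold) is assigned only if *all* its markers agree on one
chromosome. Markers on two chromosomes produce a conflict record — the
signature of either a chimeric scaffold, a wrong join, or a real derived
rearrangement — and no assignment. A majority vote would silently convert
assembly errors into confident placements, which is exactly the failure
mode this stage exists to catch. Coverage tables divide anchored bp by
externally supplied estimated chromosome sizes (the estimates are an
input, not something this package can derive), report Mb to one decimal,
and always recompute totals from rows. Flpter values (fractional length
from the p terminus, 0 at the p end) order units along chromosomes.

### Comparative maps and rearrangement counts

A unit's homolog is the reference chromosome carrying the plurality of
its mapped genes; ties are flagged unknown (`"Un"`) and excluded from
event counting rather than guessed. Along each target chromosome (units
ordered by Flpter), the dominant homolog is chosen by anchored bp — not
unit count, which many tiny scaffolds would distort — and each maximal
run of foreign homology counts as one interchromosomal rearrangement.
This run-based definition is an operationalisation: with large parts of
both genomes unanchored, counts are conservative lower bounds.

Intrachromosomal comparison counts order breakpoints, not inversion
distances: the aim is to report the presence and position of
rearrangements, not a minimal event scenario. Both unit orders are capped
with virtual chromosome ends; a breakpoint is a capped target adjacency
absent from the capped reference adjacency set, minimised over the two
reference orientations. This gives 0 exactly for identity and full
reversal (an uncapped count would miss terminal rearrangements; an
unminimised capped count would spuriously penalise whole-chromosome
reversal), and is always 0 for two or fewer units.

### Ancestral karyotypes

Karyotype comparisons across species with sparse, unequal cytogenetic
data are encoded as *pairwise co-location characters*: for every pair of
homology segments found together on a chromosome in at least one species,
each species is `together`, `apart`, or `missing`. Pairwise characters —
rather than whole-karyotype states — match the structure of the
underlying argument ("these two segments co-locate in every species
mapped so far") and degrade gracefully under missing data: a `missing`
leaf contributes the full state set to Fitch parsimony and can never
force a change.

`fitchAncestralStates()` is the standard two-pass algorithm on a rooted
binary tree. The downward pass computes the exact set of states each node
takes in at least one most-parsimonious reconstruction; a node with both
states possible is reported `ambiguous`, never resolved silently. The
root is anchored to a designated outgroup tip's state, polarising events:
an `apart → together` transition on a branch is a fusion, the reverse a
fission. Because characters are reconstructed independently, one physical
fusion of multi-segment chromosomes appears as several pairwise fusion
characters on the same branch; branch event lists should be read as
evidence bundles, not event tallies (bounds like "at least five fusions"
remain valid). `assembleAncestor()` rebuilds a node's chromosomes by
union-find over its `together` characters; an `apart` pair landing in one
component is reported as an inconsistency with the components left
standing, again because independent pairwise reconstruction need not be
globally consistent. Segments are taken to be present at a node when
observed in at least one descendant leaf.

### The bundled squamate example

`inst/extdata/` ships a rooted tree (seven squamates and an archosaur
outgroup, internal nodes labelled Squamata/Toxicofera/Iguania, etc.) and
`squamate_profiles_synthetic.tsv`, a species × chromosome × segment
matrix. The matrix is a synthetic encoding — curated from the published
comparative-mapping narrative for these species rather than copied from
any deposited table — using chicken-homology segment labels. It encodes:
the amniote-like outgroup with 11 macrochromosome-derived segments; the
squamate-stem fusions (the chicken-6/9 analogue pair, and a fragment of
the fissioned chicken-13 microchromosome joining a macrochromosome, with
that fragment unmapped in the dragon and the butterfly lizard); five
Toxicofera-stem fusions including chicken 1p+4q and the chicken 27
microchromosome joining chicken 2p; the iguanian fusion of chicken 1q
with the 6/9 chromosome; and the ophidian fission separating most of
chicken 4q from 1p. Reconstruction from these leaves yields 11 → 10 → 7 →
6 macrochromosome ancestors along the amniote–squamate–toxicoferan–
iguanian path. One deliberate choice: published accounts describe four of
the five toxicoferan fusions as macro–macro, but 10 − 4 macro–macro
fusions cannot leave 7 macrochromosomes; the encoding uses three
macro–macro plus two micro-involving fusions so that the stated ancestor
karyotype sizes (10, 7, 6) — the quantities the reconstruction is checked
against — are all simultaneously satisfiable.

## The simulator: what it emulates and what it does not

`simulateGenomes()` draws all randomness from one seeded stream in a fixed
documented order (gene lengths, gaps, reference-A events, reference-B
events, scaffold cuts, dropout A, dropout B, markers), so a configuration
is a complete specification of its output. Defaults model a small
agamid-like system: 600 genes on 6 macrochromosomes, five inversions, two
reciprocal translocations and one fusion and fission per reference
lineage, 60 target scaffolds, 10 % ortholog dropout per reference, and on
average one anchor marker per two scaffolds. Gene lengths are uniform
1–20 kb with 0.5–5 kb gaps — arbitrary but harmless, since every
downstream computation uses ordinals only. Scaffold cuts are sampled
uniformly over inter-gene boundaries *subject to every scaffold keeping at
least two genes*: a physical single-gene scaffold is indistinguishable
from an orphan and would be skipped by design, so single-gene scaffolds
are introduced only deliberately, by `plantOrphans()`, which re-cuts a
multi-gene scaffold into flank/orphan/flank and updates the truth set.
Event application order within a lineage is fissions, fusions,
translocations, inversions; each event is logged with replayable
parameters, and the lineage's breakpoint set is defined as ancestral gene
adjacencies absent from the final derived genome.

What passing tests on these simulations shows: the join/consensus/chain
logic is exact under its assumptions (precision and recall are 1.0 when
the references carry no rearrangement and no dropout; consensus joins
never bridge a lineage breakpoint; recall degrades monotonically with
dropout). What it does not show: robustness to the things real data adds
— annotation errors, paralogy mistaken for orthology, assembly chimerism,
unequal reference quality, and lineage-specific gene loss that is not
independent across neighbouring genes. The marker model is similarly
idealised (uniform positions, error-free chromosome calls); the
conflict-detection guarantees say what happens when a wrong call occurs,
not how often it occurs.

## Numerical and scale choices

Test and acceptance problem sizes (tens of scaffolds, hundreds of genes,
20–50 replicate seeds, trees to 6 leaves for exhaustive enumeration) were
chosen so that brute-force oracles — maximal-run enumeration for HSBs,
2^k labelings for parsimony, full permutation sets for breakpoints — are
exact and fast; the algorithms themselves are linear or near-linear in
genes and scale far beyond that. All ranking ties anywhere in the package
(ordinals, block ranking, cycle breaking, dominant homolog) break
lexicographically, so every output is reproducible byte-for-byte; the
pipeline's manifest of md5 hashes makes that checkable. Degenerate inputs
are defined rather than accidental: empty maps give empty block lists,
single-gene blocks have equal endpoints, empty chromosomes report zero
coverage, markerless units stay unassigned, and two-unit orders have zero
breakpoints by construction.

## Known limitations

- Gene order within a super-scaffold is assumed, not demonstrated: joins
  assert adjacency, and internal rearrangement in the target lineage
  would be invisible until markers contradict it.
- No gap sizes are estimated between joined scaffolds; sizes are member
  sums.
- Interchromosomal event counts depend on anchoring completeness and are
  lower bounds under the maximal-foreign-run definition.
- Parsimony is unweighted Fitch; fusions and fissions are treated as
  equally costly, and likelihood models of chromosome number evolution
  are out of scope.
- The bundled squamate matrix is an encoding of narrative mapping
  statements, adequate for exercising the reconstruction machinery and
  reproducing the headline ancestor karyotypes, but not a substitute for
  the full underlying mapping data.
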