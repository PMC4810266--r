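---
title: "Delineating giant-virus lineages from comparative genomics"
author: "panlineage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating giant-virus lineages from comparative genomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panlineage)
```

## The problem

Families of large double-stranded DNA viruses — the Marseilleviridae are the
motivating example — are internally structured into *lineages*: groups of
isolates whose proteins are nearly identical to each other (~97% mean amino-acid
identity) but clearly diverged from other groups (<73%). When a new isolate is
sequenced, the question is whether it belongs to a known lineage or founds a
new one. `panlineage` implements the full comparative-genomics argument used to
answer that question: reciprocal-best-hit orthology, average amino-acid
identity (AAI), paralogous families, pan-/core-genome accumulation, phyletic
presence/absence clustering, a core-gene phylogeny with an SPR supertree, and
a decision rule that combines them.

The package is exercised end to end on simulated genome families with known
truth, so every stage is testable without downloading anything. Real annotated
genomes (GenBank flat files, or FASTA + GFF3) run through the identical code
path.

## The statistics at the core

**Alignment.** All similarity is measured by optimal local alignment
(Smith–Waterman) with affine gaps under gapped-BLASTp conventions: BLOSUM62,
gap open 11, gap extend 1 (a gap of length $L$ costs $11 + L$), identity
defined as matches over aligned columns *including* gap columns, and
Karlin–Altschul e-values $E = mn\,2^{-S'}$ with $S' = (\lambda S - \ln K)/\ln 2$,
$\lambda = 0.267$, $K = 0.041$. Traceback is deterministic (diagonal over up
over left), so every downstream number is reproducible. A k-mer prefilter
(shared 5-mers) limits which pairs are aligned; in the identity regime of this
problem (orthologs at 50% identity and above) it leaves reciprocal best hits
and AAI unchanged, which the test-suite verifies against exhaustive alignment.

**Orthology.** Bona fide orthologs between two genomes are reciprocal best
hits (RBH) after thresholds of e-value $\le 10^{-5}$, identity $\ge 30\%$ and
coverage $\ge 50\%$ of *both* sequences (the strict reading of coverage).
Within-genome paralogous families are connected components of the qualifying
self-hit graph refined by Markov clustering (inflation 1.5 by default).

**AAI.** Two-way AAI is the unweighted mean (and median) of the alignment
identities of the RBH pairs; one-way AAI uses per-query best hits and is
asymmetric. Pairs with no qualifying orthologs are reported as missing, never
as 0%.

**Pan/core genome.** Proteins are clustered into COGs by a deterministic
centroid-greedy procedure (BLASTclust-style): longest protein first, each
protein joins the first cluster whose representative it matches at 30%
identity / 50% bidirectional coverage, else founds a cluster. Stepwise genome
inclusion yields the pan-genome (clusters present in at least one included
genome) and core genome (clusters present in all of them); single-genome
clusters count toward the pan-genome, so a genome's ORFans contribute to its
pan increment.

**Phyletics.** The presence/absence matrix over clusters is compared between
genomes by Pearson-correlation distance $d = 1 - r$ and clustered by
average-linkage (UPGMA) agglomeration. The linkage is selectable; average
linkage is the default because the analysis this mirrors did not state one.
$1-r$ (rather than $(1-r)/2$) is used and documented; it is a monotone
relabelling and does not affect the dendrogram topology.

**Phylogeny.** Five single-copy core genes (family B DNA polymerase, D6/D11
helicase, VV A18 helicase, D5 primase-helicase, major capsid protein) are
located by best qualifying hit to marker seed sequences (duplicates resolve to
the higher bit score, ties to the longer protein). Their alignments come from
an in-package progressive aligner (k-mer-distance UPGMA guide tree,
profile–profile global DP with affine gaps); distances are Kimura-corrected
protein distances $d = -\ln(1 - p - p^2/5)$ over pairwise-comparable columns;
trees are neighbour-joining with negative branch lengths clamped to zero.
NJ replaces the original approximate-maximum-likelihood engine deliberately:
only the topology enters the downstream argument, and NJ is exact on additive
distances (a property the tests pin). Bootstrap support is out of scope.

**Supertree.** The summary tree minimises the total subtree-prune-and-regraft
(SPR) distance to the per-gene trees. SPR distance is computed exactly by
(bidirectional) breadth-first search over SPR neighbourhoods — exact for the
leaf counts used here, where the whole topology space is at most 10,395 trees.
The supertree search is exhaustive for up to 7 leaves; beyond that it
hill-climbs over SPR neighbourhoods from the input trees plus random restarts
(10 by default, seeded), scoring against precomputed distance balls around
each input (radius `cap - 1`, distances truncated at `cap = 2` during the
climb). The final candidates and the input trees themselves are re-scored
with exact distances, so the reported score is exact and never exceeds that
of any input evaluated as a candidate.

**Lineage assignment.** Genomes are grouped by single-linkage on the two-way
AAI matrix at a threshold of 95%, chosen inside the empirical gap between
within-lineage (~97%) and between-lineage (<73%) identity; singleton
components are new lineages. The threshold is exposed (`within_threshold`)
because no hard cutoff is canonical. The evidence report then scores five
independent lines — synteny, AAI separation, codon-usage rank correlation,
shared-cluster proportions, and pan-genome increments — as concordant or
discordant with the partition, with a majority verdict. Codon usage never
feeds the partition itself; it is reported only.

## The simulator and what it does (not) capture

`simulation_config()` defaults encode the study conditions the package is
designed for:

| parameter | default | meaning |
|---|---|---|
| `lineage_tree` | `((A:0.16,B:0.17):0.05,(C:0.15,D:0.21):0.04);` | lineage ancestors; branch lengths in substitutions/site |
| `n_genomes_per_lineage` | A=4, B=1, C=2, D=1 | eight genomes, mirroring a real family with one founding member |
| `ancestral_gene_count` | 480 | gene copies in the ancestor (including paralogs) |
| `paralog_expansion` | 30 families, largest 14 copies | ~94 paralogous copies |
| `orfan_count` | 29 | unique random-composition proteins per genome |
| `gene_birth_rate` / `gene_death_rate` | 60 / 80 per unit branch | lineage-specific gene content |
| `within_lineage_target_identity` | 97% | pairwise within-lineage protein identity |
| `between_lineage_target_identity_range` | 56–73% | band the tree's implied identities must respect |
| `inversion_rate` | 12 per unit branch | gene-order rearrangements |
| `gc_target` | 43–45% | genome G+C, met by solving synonymous-codon weights |

The defaults were chosen once from the descriptive statistics of the
Marseilleviridae (genome sizes 346–387 kb, ~450–500 genes, coding density
~97%, a slight minus-strand excess, G+C ~43%) and are not revisited per run.
With these settings a new-lineage genome adds ≈ 29 ORFan clusters plus ~12
newly born families to the pan-genome (≈ 41 clusters), while a same-lineage
genome adds ≈ 30 — reproducing the qualitative pan-genome signature that a
founding member of a new lineage produces a visibly larger increment.

Protein divergence uses per-site substitutions with a fixed
BLOSUM62-derived exchangeability kernel (conservative replacements
favoured); per-branch retention $e^{-t}$ multiplied along paths gives
pairwise identities within ±3 points of target. Lineage-specific synonymous
codon-weight perturbations create codon-usage signatures without moving
amino-acid usage. Emission is a pure function of the seed and the gene
content, so identical configurations are byte-identical, including the
GenBank output.

What the simulator does *not* emulate — and hence what green tests do not
demonstrate about real data: indel evolution inside genes (alignments of
simulated orthologs are gap-free), low-complexity and compositionally biased
regions, horizontal transfer from outside the family, annotation error
(mispredicted starts, missed genes), and real intergenic sequence structure.
The alignment and clustering machinery handles gaps and partial coverage, but
its behaviour under heavy indel load is only exercised by the toy tests, not
by the family-scale simulations.

## Numerical choices and degenerate inputs

* Identity denominators include gap columns; coverage is computed per
  sequence and both must pass. Ties in best-hit selection break by higher
  identity then lexicographic subject id.
* The greedy clusterer's candidate prefilter relaxes its shared-k-mer
  threshold for short sequences (`floor(min_kmers/50)`), so short genuine
  homologs are still aligned.
* A genome pair with zero qualifying orthologs yields a missing AAI cell;
  `assign_lineages()` refuses missing cells unless told to treat them as
  below threshold.
* Zero-variance phyletic profiles (a genome present in every cluster) have
  undefined Pearson distance and are signalled, not silently imputed.
* Kimura's correction diverges for $p \ge$ ~0.85; such pairs are flagged
  missing rather than truncated.
* UPGMA and NJ sort labels before agglomeration, making results invariant to
  input order; hill-climbing ties break by canonical topology key.
* Origin-spanning CDS on circular genomes are stored with `start > end` plus
  a `wraps_origin` flag; statistics count their bases once.
* Translation uses the standard genetic code throughout.

## Problem sizes

The shipped tests and the acceptance script run entirely on simulated data at
the scale the package targets: families of 8 genomes × ~500 proteins,
full all-vs-all orthology (~28 genome pairs, ~10^3 alignments per pair after
prefiltering), greedy clustering of ~4,000 proteins, and 20 independent
families for the recovery and calibration sweeps. Exhaustive tree machinery
(SPR distance by BFS, supertree by full topology scan) is used up to 7 leaves
and validated against independent ape-based tree surgery.

## Known limitations

* The aligner is exact but plain dynamic programming; it is adequate at this
  package's scale and is not a drop-in replacement for BLAST on large
  databases.
* Greedy clustering granularity is engine-dependent; absolute COG counts are
  comparable only within one engine, which is why cluster-count figures are
  treated as approximate whenever engines differ.
* The SPR supertree hill-climb (needed above 7 leaves) is a local search; the
  returned score is exact but global optimality is only guaranteed in the
  exhaustive regime.
* Lineage assignment is single-linkage on AAI: a single intermediate genome
  can chain two lineages. The evidence report surfaces, but does not resolve,
  such conflicts.

## A worked sketch

```{r example, eval = FALSE}
cfg <- simulation_config(seed = 42)
sim <- simulate_family(cfg)
res <- run_pipeline(pipeline_config(sim, outdir = tempfile()))
res$lineage$partition
res$lineage$report
```

The partition recovers the generating lineages exactly (adjusted Rand index 1
against the simulator's truth in the calibrated regime), and the report's
five evidence lines are concordant on clean families. The same
`run_pipeline()` call accepts a character vector of GenBank paths for real
genome sets.
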