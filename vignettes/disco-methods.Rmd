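---
title: "Decomposing multicopy gene family trees: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing multicopy gene family trees: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(disco)
```

## The problem

Gene duplication and loss (GDL) leave gene family trees with several
leaves per species. Most species-tree estimation machinery — quartet
summary methods, distance methods, concatenation — expects at most one
leaf per species. This package turns multicopy ("MUL") gene family trees
into leaf-disjoint single-copy trees, prioritizing one large output tree
while keeping every split-off clade, so that standard methods apply with
as little information loss as possible.

## Rooting and tagging

All decisions are topological; branch lengths are parsed and re-emitted
but never consulted.

An internal vertex of a rooted binary gene tree is tagged a
**duplication** iff the species sets of its two child subtrees intersect,
which for binary trees is equivalent to the vertex being the least common
ancestor of two copies of one species; otherwise it is a **speciation**.

Rooting chooses, among all `2n - 3` edges of the unrooted tree, an edge
minimizing duplications + inferred losses of the resulting tagged tree
(`best_root()`). Because no reference species tree is available at this
stage, a loss-count convention is needed; this package charges, at each
duplication vertex with child species sets `A` and `B`, one loss per child
missing a species present under the vertex:
`[A ≠ A∪B] + [B ≠ A∪B]`. This penalizes asymmetric duplications and
leaves duplication-free trees at score zero on every edge. The convention
is deliberately isolated inside the scoring routine: every correctness
property of the decomposition depends only on the tagging, not on the
loss convention, and alternative conventions could be swapped in without
touching anything else. The implementation scores every edge by direct
rerooting; the test suite checks it against an independent recursive
scorer on random trees, which is the defining semantics.

Determinism matters for reproducible pipelines, so ties among
minimum-score edges are broken by a canonical edge order derived from the
sorted leaf labels of each edge's split, and "left/right" children are
ordered by the lexicographic order of their sorted leaf-label multisets.

## Decomposition

Vertices are visited in postorder. At each vertex *originally* tagged as
a duplication, the child clade currently containing fewer distinct
species is detached (current = after earlier detachments below; species
are recounted, tags are not). Ties go to fewer leaves, then to the
canonical right child. Each detachment suppresses the resulting degree-2
vertex, so outputs are valid trees — specifically, each output is the
input tree restricted to the output's leafset. For binary inputs this
yields exactly `#duplications + 1` pairwise leaf-disjoint single-copy
trees covering the whole input leafset.

Two sizing conventions from downstream use: with summary methods, output
trees with fewer than 4 species are discarded
(`filter_by_size(d, 4)`); for concatenation nothing is discarded, so
coverage stays at 100%. "Size" is measured in distinct species (with a
leaf-count secondary tie-break); the alternative — counting leaves — is
indistinguishable on the motivating worked example, and the choice is
documented rather than claimed canonical.

## The MI baseline

`mi_decompose()` implements the maximum-inclusive-subtree strategy:
repeatedly cut out, over all edges of the current unrooted tree, a
duplicate-species-free subtree of maximum species count, until none with
at least `min_species` species remains; leftover fragments are discarded
but still count against coverage. It needs no rooting, is more
conservative, and on duplicate-free families coincides with the
decomposition above. Its tie-breaks (more leaves, then canonical label
order) are this package's own, chosen for determinism.

## Supermatrix construction

For concatenation analysis, `split_alignment()` places each family's
aligned sequences into one sub-alignment per output tree (full alignment
width, rows relabeled to species — valid because outputs are
single-copy), and `build_supermatrix()` concatenates all sub-alignments
over sorted species rows, filling absent species with `-`. Note that a
family decomposed into *k* subsets contributes *k* partitions of its full
alignment width; gappiness counts both fill gaps and alignment-internal
gaps. Partitions are written as 1-based inclusive RAxML-style lines
(`DNA, fam1_2 = 11-15`). Output is byte-deterministic given inputs and
their order.

## Evaluation conventions

* Robinson–Foulds distances are normalized by `2n − 6`, the maximum
  symmetric difference for two binary trees on `n` shared leaves;
  multicopy trees are compared after per-copy label uniquification.
* Orthology: a decomposition calls a pair of gene copies orthologous iff
  they share an output tree; a tagged tree calls them orthologous iff
  their LCA is speciation-tagged. Decomposition calls are always a subset
  of tagged-tree calls on the same tree, which is why the decomposition
  trades recall for precision.
* `precision = TP/(TP+FP)` and `recall = TP/(TP+FN)` return 1 on a zero
  denominator so that batch summaries stay finite; affected entries are
  identifiable from the attached counts. Because pooling over all pairs
  and averaging per family can differ, `orthology_accuracy()` reports
  both (`*_pooled`, `*_macro`).

## The simulator, and what it does and does not emulate

`simulate_species_tree()` draws Yule trees with exponential branch
lengths. `simulate_gene_family()` runs a birth–death copying process down
the species tree: duplications (rate `dup_rate` per unit branch length)
spawn an independent daughter lineage continuing from the duplication
point — gene copies evolve independently — and losses (rate `loss_rate`)
prune lineages. Surviving internal vertices carry their true event label,
which defines true orthology (pairs whose MRCA event is a speciation).
Families with fewer than 4 surviving copies are regenerated, up to a
reported retry cap.

Rates are free-scale (per unit species-tree branch length), not
calibrated to any published mutation-rate units, so absolute family sizes
in published tables are not expected to be matched. The defaults
(`dup_rate = 0.2`, `loss_rate = 0.2` on a unit-birth Yule tree) give
families whose leaf count modestly exceeds the species count — the
moderate-duplication regime.

Two real-data features are deliberately not simulated: incomplete lineage
sorting (the multispecies coalescent layer) and sequence-level estimation
error. Estimation error is approximated topologically by random NNI moves
(`perturb_nni()`, with `calibrate_nni()` searching the move count that
reaches a target mean normalized RF distance); ILS is absent. Passing the
consistency checks therefore demonstrates correctness of the
decomposition under GDL-only discord with correct tagging — the regime in
which the method's guarantee is stated — and says nothing about
robustness to ILS or alignment error on real data. `clade_based_missing()`
reproduces the clade-based missing-data scheme: an affected family keeps
only species of a uniformly drawn species-tree clade containing at least
20% of the species (the root clade qualifies, so near-1 thresholds leave
families intact).

## Problem sizes and degenerate inputs

The shipped checks run at desk scale, chosen as the smallest sizes at
which the properties are meaningful rather than as any external
constraint: 500 random MUL-trees (≤ 60 leaves) for the structural
invariants, 200 trees (≤ 40 leaves) for exhaustive rooting-oracle
equivalence, 200 simulated families on 16 species for the
species-tree-restriction consistency property, and 12 × 25 families on
101 species for the missing-data statistic. The acceptance script
recomputes unfiltered coverage over 500 simulated families on 24 species.

Degenerate inputs are handled explicitly: 1- and 2-leaf output trees are
representable and serializable; 2-leaf families parse but cannot be
rooted; polytomies must be resolved (randomly, seeded) before tagging;
empty decompositions after filtering are legal with coverage 0.

## Known limitations

* The loss-count convention is a documented substitute for an unspecified
  original; rooting choices can differ from other implementations on
  trees where loss terms dominate, though tagging (and hence everything
  downstream of a fixed rooting) is unambiguous.
* Whether "smallest child clade" should count species or leaves is
  likewise underdetermined; this package counts species.
* `best_root()` scores all edges by rerooting (quadratic-ish in tree
  size); it is comfortable to a few hundred leaves but not tuned for
  thousands.
* Orthology truth requires simulator input; no reconciliation against a
  known species tree is provided.
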