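# disco

Species-tree pipelines built on single-copy gene trees (ASTRAL, ASTRID,
concatenation) cannot directly use *multicopy* gene family trees — trees in
which gene duplication has left several leaves per species. **disco**
decomposes such MUL-trees into leaf-disjoint single-copy trees so that any
standard downstream method can consume them, and ships everything needed to
test the procedure end to end: an MI baseline, a supermatrix builder for
concatenation analysis, evaluation statistics, and a gene
duplication/loss (GDL) simulator. It is aimed at phylogenomics
practitioners working with gene families that contain paralogs.

## Method

For each binary gene family tree `t` (polytomies are resolved randomly):

1. **Rooting.** Every edge of `t` is scored by the number of duplication
   events (plus inferred losses) that tagging the tree rooted on that edge
   implies; `t` is rooted on a minimum-score edge.
2. **Tagging.** An internal vertex `v` with child species sets
   `S(v_l)`, `S(v_r)` is tagged a *duplication* iff
   `S(v_l) ∩ S(v_r) ≠ ∅` — i.e. iff `v` is the LCA of two copies of some
   species — and a *speciation* otherwise.
3. **Decomposition.** Visiting vertices in postorder, each
   duplication-tagged vertex is resolved by detaching the child clade
   currently containing fewer distinct species (ties: fewer leaves, then
   the canonical right child). The detached clades plus the residual tree
   are the output.

The output trees are pairwise leaf-disjoint, each contains at most one
leaf per species, their union covers the entire input leafset (100%
coverage before any filtering), and there are exactly
`#duplications + 1` of them. Under a GDL-only model with correct tagging,
every output tree is the species tree restricted to its species — the
property that makes quartet-based pipelines built on this decomposition
statistically consistent.

For concatenation analysis, each family's alignment is carved along the
decomposition, rows are relabeled to species, and all pieces are
concatenated into a gap-filled species × sites supermatrix with RAxML-style
partition intervals.

## Worked example

```r
library(disco)
fams <- read_gene_trees(
  text = "(((a_1,(b_1,(c_1,d_1))),((a_2,(b_2,c_2)),(e_1,f_1))),(d_2,(e_2,f_2)));")
x <- fams[[1]]
x
#> Gene family tree 'fam1': 12 gene copies, 6 species

rooted <- best_root(x)
rooted
#> Tagged gene family tree 'fam1': 12 gene copies, 6 species; 2 duplication vertices, 3 inferred losses

d <- disco_decompose(rooted)
summary(d)
#> DISCO decomposition of 'fam1'
#>   trees:         3
#>   duplications:  2
#>   coverage:      1
#>   sizes:         4 3 5

writeLines(write_gene_trees(lapply(d$trees, relabel_to_species), unroot = TRUE))
#> (a,b,(c,d));
#> (d,e,f);
#> (a,(b,c),(e,f));
```

The family's 12 gene copies over species `a`–`f` contain two duplication
vertices; the decomposition yields three single-copy trees of 4, 3 and 5
species whose leafsets partition the input (coverage 1). The relabeled
trees are ready for any single-copy species-tree method.

From a shell, the same pipeline is available as

```sh
Rscript inst/scripts/disco.R decompose -i trees.nwk -o out.nwk \
    -d "_" -f 1 --min-species 4 --stats stats.tsv
```

with sibling subcommands `mi` (the maximum-inclusive-subtree baseline) and
`simulate` (the GDL simulator).

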