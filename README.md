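# phyloconflict

Dissecting gene-tree conflict, concordance, and gene duplications across a
species tree.

Phylogenomic datasets — hundreds to thousands of gene-family (homolog)
trees from transcriptomes or genomes — routinely hide deep disagreement
beneath a species tree whose every edge has 100% bootstrap. The
disagreement matters: it carries the signature of incomplete lineage
sorting, hybridization, hidden paralogy, gene and genome duplication, and
plain lack of signal. `phyloconflict` is for researchers who want to
dissect that conflict rather than average over it. It works directly on
rooted homolog trees, so multiple gene copies per taxon and partially
overlapping taxon sets are handled natively.

## What it computes

Every internal edge of a rooted homolog clade induces a **rooted
bipartition** — the clade's taxa (ingroup, gene copies collapsed) against
the remaining taxa of that tree (outgroup); `(A,A,B)|(C,D,E)` is recorded
as `(A,B)|(C,D,E)`. Against a species bipartition *s*, a homolog
bipartition *h* is

- **concordant** iff in(*h*) ⊆ in(*s*) and out(*h*) ⊆ out(*s*) — mapped to
  the shallowest such *s*;
- **conflicting** iff in(*h*)∩in(*s*), in(*h*)∩out(*s*) and
  in(*s*)∩out(*h*) are all non-empty;
- otherwise uninformative for *s* (the normal case under partial overlap).

Conflicting statements at each node are grouped into alternative
resolutions by set containment, and each edge is scored with **internode
certainty**

> ICA = 1 + Σₙ P(Xₙ) log_b P(Xₙ),

over the focal and grouped alternative frequencies (b categories); 1 means
no conflict, 0 maximal evenness of conflict. Gene **duplications** are
nodes whose children share ≥ 2 taxa with multiple copies, filtered locally
by bootstrap and mapped onto the species tree where congruent. A
**multispecies-coalescent simulator** generates null conflict profiles on
the species tree (branch lengths in coalescent units) to ask whether the
observed alternatives look like ILS.

## Worked example

A synthetic dataset with known ground truth: 120 homolog trees on 8 taxa,
30 of them (25%) carrying an alternative resolution at species node 2, six
carrying a planted gene duplication of the node-3 clade.

```r
library(phyloconflict)

fx <- generate_fixture(fixture_spec(
  n_taxa = 8, n_homologs = 120,
  conflict_rate = 0.25, conflict_nodes = 2,
  dup_plan = data.frame(node_id = 3, n_events = 6),
  seed = 42))

nc <- map_conflicts(fx$species_tree, fx$gene_trees, min_support = 50)
nc
#> conflict/concordance summary: 120 homologs on 6 species-tree nodes (filter >= 50%)
#>   node_id n_concordant n_conflicting n_grey  ica
#> 1       1          120             0      0 1.00
#> 2       2           90            18     12 0.35
#> 3       3          120             0      0 1.00
#> 4       4          120             0      0 1.00
#> 5       5          120             0      0 1.00
#> 6       6          120             0      0 1.00
```

Node 2 is the planted conflict: 90 of 120 homologs support the species
resolution, 18 support an alternative with bootstrap ≥ 50, and 12 more
carry the alternative only on edges below the filter (grey). The ICA of
0.35 reflects a 90:18 split between the focal statement and one
alternative. The alternative itself is a single grouped statement:

```r
nc$alternatives[["2"]]
#>   rank n_homologs n_biparts  ingroup       outgroup
#> 1    1         18        18 t1;t7;t8 t2;t3;t4;t5;t6
```

All six planted duplications are recovered and mapped to the right node:

```r
map_gene_duplications(fx$species_tree, fx$gene_trees, min_support = 50)
#> gene duplications: 6 total across 6 homologs; 6 mapped, 0 unmapped
#>  node_id n_duplications n_homologs
#>        3              6          6
```

`write_conflict_outputs()`, `write_duplication_outputs()` and
`write_null_outputs()` export every per-node table as TSV plus node-key
and ICA-labeled newick trees. A command-line wrapper with
`concord` / `dups` / `simulate` subcommands is installed at
`inst/cli/phyloconflict.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/phyloconflict.R", package="phyloconflict"))')" \
  concord -s species.tre -d genetrees/ -b 50 -o run1
```

See `vignettes/conflict-analysis.Rmd` for the full account of the rules,
the ICA extension to partial taxon overlap, the duplication criterion, the
coalescent simulator's assumptions, and known limitations.

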