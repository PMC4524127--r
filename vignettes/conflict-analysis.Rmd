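---
title: "Mapping gene-tree conflict, concordance, and duplications onto a species tree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping gene-tree conflict, concordance, and duplications onto a species tree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloconflict)
```

## The problem

Phylogenomic datasets built from transcriptomes or genomes carry hundreds to
thousands of gene-family (homolog) trees, and those trees disagree — with the
species tree and with each other — because of incomplete lineage sorting
(ILS), hybridization, hidden paralogy, low phylogenetic signal, and gene
duplication. A species tree with 100% bootstrap on every edge can still sit
on top of massive underlying conflict. This package dissects that conflict:
it decomposes rooted homolog trees into rooted bipartitions, maps each one
onto a species tree as concordant or conflicting, groups the conflicting
statements into alternative resolutions, scores each species-tree edge with
internode certainty (ICA), counts gene duplications, and simulates what the
conflict profile *should* look like if ILS alone were responsible.

Homolog trees are used directly — not inferred orthologs — so multiple gene
copies per taxon are expected, taxon sets overlap only partially across
loci, and duplication signal is retained rather than filtered away.

## Rooted bipartitions

Every internal non-root node of a rooted ingroup homolog clade induces a
*rooted bipartition*: the taxa of its clade toward the tips (the ingroup)
against the remaining taxa of that tree toward the root (the outgroup).
Rooting is what distinguishes a grade from a clade, which unrooted splits
cannot. Gene copies collapse to taxon names, so a clade with tips
`A@1, A@2, B` against remaining taxa `C, D, E` is recorded as
`(A,B | C,D,E)`. Bipartitions whose collapsed ingroup shrinks to a single
taxon, and the root's bipartition (empty outgroup), carry no grouping
information and are dropped.

Tip labels encode taxon plus copy with a configurable delimiter (default
`"@"`, text before the first delimiter is the taxon); labels without the
delimiter are themselves taxon names, so species trees need no relabeling.

## Concordance and conflict

For a homolog bipartition $h$ and a species bipartition $s$:

* $h$ is **concordant** with $s$ iff
  $\mathrm{in}(h) \subseteq \mathrm{in}(s)$ and
  $\mathrm{out}(h) \subseteq \mathrm{out}(s)$;
* $h$ **conflicts** with $s$ iff all three intersections
  $\mathrm{in}(h) \cap \mathrm{in}(s)$,
  $\mathrm{in}(h) \cap \mathrm{out}(s)$ and
  $\mathrm{in}(s) \cap \mathrm{out}(h)$ are non-empty.

The two are mutually exclusive (the ingroup and outgroup of $s$ are
disjoint), and a pair that is neither is *uninformative* for $s$ — the
normal case under partial taxon overlap. When $h$ is concordant with
several nested species bipartitions it is mapped to the shallowest one
(furthest from the root); under polytomies several equally shallow
candidates can exist, and the tie is broken deterministically by smallest
ingroup, then lexicographic ingroup. Species-tree nodes are numbered in
preorder from the root (0-based, the root is 0) and that numbering is
emitted in a node-key tree so every table can be read back onto the
topology.

Per species node, each homolog votes at most once per category: concordant
if any of its passing bipartitions maps there, conflicting if any passing
bipartition conflicts there, and "grey" (below-filter informative) if its
only informative bipartitions for the node fail the bootstrap filter. The
headline counts are homolog counts, not bipartition counts, because one
gene tree can hit a node with several edges. Pie-chart proportions use as
denominator the homologs informative for the node at *any* support level,
split into disjoint slices: concordant, top alternative, remaining
alternatives, grey. The bipartition pool reports both the total number of
extracted bipartitions and the number of unique statements, since either
total can be the quantity of interest.

### Bootstrap filtering

The bipartition filter ignores edges with support *below* the threshold
(default 50%), so an edge at exactly 50 passes. Edges carrying no support
pass by default — absence of a bootstrap value is not evidence of low
support — and `missing_support_fails = TRUE` inverts that policy. Numeric
newick node labels in $[0,1]$ are read as proportions and rescaled to
percent; values in $(1,100]$ are percentages already; the normalization is
idempotent. Note one deliberate boundary asymmetry elsewhere: the
per-homolog statistic "proportion of supported edges"
(`homolog_stats()`) uses a strict "greater than" its threshold, matching
the usual phrasing of that summary, while the filter keeps
exactly-threshold edges.

## Grouping conflicting alternatives

All conflicting bipartitions at a node are compared all-by-all and grouped
when one statement is contained completely within the other
($\mathrm{in}(b_1) \subseteq \mathrm{in}(b_2)$ and
$\mathrm{out}(b_1) \subseteq \mathrm{out}(b_2)$, or vice versa), as happens
when taxon sampling differs between loci. Groups are built greedily in
descending order of statement frequency (ties lexicographic): a statement
compatible with the representatives of several existing groups joins each
of them, so one homolog can legitimately appear in more than one
alternative, and the cumulative sum of group counts can exceed the number
of conflicting homologs. Each group reports its count of distinct
supporting homologs.

## Internode certainty

For each species edge the ICA is computed from the homolog-deduplicated
focal count (the node's concordant homologs) and the grouped alternative
counts:

$$\mathrm{ICA} = 1 + \sum_{n=1}^{b} P(X_n) \log_b P(X_n),$$

where $b$ is the number of categories with positive counts, including the
focal one, and $P(X_n)$ are their proportional frequencies. With a single
category ($b = 1$) the value is defined as 1; equal frequencies give 0.
Computed this way the value lies in $[0,1]$; the classical signed variant
can go negative when an alternative outnumbers the focal bipartition, so
nodes in that situation are flagged (`alt_exceeds_focal`) rather than
given a negative score.

## Gene duplications

Homolog trees are walked in postorder. A node is a duplication when at
least two taxa each have gene copies in at least two of its children's
subtrees (for a binary node: the left/right descendant taxon sets share two
or more taxa). The union of descendant taxon sets is carried upward so
nested duplications are each found once per level. Requiring two shared
taxa makes the method conservative toward the tips, where often only one
taxon retains both copies. The bootstrap filter is local: the focal node
and each *internal* child must pass (tips carry no support and are exempt —
otherwise no tip-adjacent duplication could ever qualify).

Only duplications congruent with the species tree are mapped: the event's
taxon union against the rest of its homolog's taxa must be concordant with
some species bipartition, and the event is placed on the shallowest such
node; when the union spans the homolog's whole taxon set the event is
placed on the MRCA of the union. Events are reported in two tiers — total
detected and mapped — and the MRCA placement is recorded alongside the
concordance placement in the events table because the two can differ under
missing taxa.

## Coalescent null distributions

To judge whether a node's conflict profile is compatible with ILS alone,
gene trees are simulated under the multispecies coalescent on an
ultrametric species tree whose branch lengths are in coalescent units
(proportional to the product of effective population size and mutation
rate). One lineage starts per species tip (a single sampled allele per
species); within each branch, $k$ lineages coalesce at rate
$\binom{k}{2}$ per coalescent unit; lineages surviving to the root keep
coalescing above it (standard Kingman continuation). No per-branch
population sizes are modeled — the branch lengths *are* the model, matching
how such simulators are normally driven. The simulator is validated
against the closed-form probability that a three-taxon gene tree contains
the species clade, $1 - \tfrac{2}{3}e^{-t}$ for an internal branch of
length $t$.

`conflict_null()` rescales the species tree to several root heights
(defaults 10, 20, 30 — deep coalescence from frequent to rare), simulates,
maps the simulated trees back onto the topology, and emits the per-node
ranked alternative-frequency curves plus their pointwise min–max band
across heights. The band is descriptive, mirroring the visual
within/outside judgment such plots support; no hypothesis test is claimed.
Empirical species trees must be supplied already ultrametric in coalescent
units: penalized-likelihood dating is an independent method and outside
this package's scope, so only `rescale_root_height()` is provided.

`sim_pure_birth()` grows Yule trees for simulation studies; with unit
birth rate the expected root height of an $n$-tip tree is
$\sum_{k=2}^{n} 1/k$, which the test suite checks by Monte Carlo.

## The synthetic fixture generator

`generate_fixture()` produces homolog sets with known ground truth: copies
of a simulated species tree in which a chosen fraction of homologs is
NNI-perturbed at named species nodes (a discrete alternative resolution —
the conflicting homolog then conflicts at exactly that node and is
concordant everywhere else), gene duplications are planted by duplicating
a species clade into a cherry of two copy-labeled subtrees, bootstrap
supports are drawn from separate ranges for concordant and planted
conflicting edges, and tips can be randomly pruned. The generator writes a
ledger of the exact per-node counts, alternative groups, ICA values and
duplication placements it planted (stated for filter 0; exact only without
pruning), and every analysis module is tested against it.

What the fixtures emulate is deliberately discrete: one alternative
topology per perturbed node, clean planted duplications, supports
independent of branch lengths. They do not emulate estimation error,
saturation, alignment noise, rate heterogeneity, or the continuous spectrum
of ILS alternatives — the coalescent simulator covers that last aspect.
Passing the fixture tests therefore demonstrates that the bookkeeping and
set algebra are exact, not that the method is robust to every property of
real transcriptome data.

## Numerical and design choices

* Trees are ape `phylo` objects; support rides in internal node labels and
  is parsed on demand, so all ape tree surgery remains available.
* Ultrametricity is checked with a relative tolerance of $10^{-6}$;
  rescaling hits the target height to $10^{-9}$.
* Rerooting for ingroup extraction uses the outgroup tip topologically
  closest to the current root, ties broken by lexicographic tip label —
  a deterministic stand-in for upstream orthology pipelines' conventions.
* Polytomies are supported end-to-end (decomposition, mapping, duplication
  detection generalizes "left and right subtree" to "at least two
  children").
* Multifurcation ties in shallowest mapping, group ordering, and
  alternative ranking are all broken lexicographically so repeated runs are
  byte-identical.
* Degenerate inputs fail loudly: duplicate tip labels, malformed newick
  (with character offset), homolog taxa absent from the species tree
  (listed by name), pruning below three tips, all-zero ICA counts.

Checks in the test suite and acceptance script use deliberately modest
problem sizes — 200-homolog fixtures on 8–10 taxa, 10,000 coalescent genes
per branch length for the three-taxon closed form, and five 20-taxon
pure-birth trees with 200 genes each for the missing-data pruning design —
sizes at which the exhaustive brute-force oracles remain tractable.

## Known limitations

* ICA under heavy missing data: when *every* gene tree is randomly pruned,
  distinct prunings of the same underlying alternative are almost never
  nested within one another, so containment grouping cannot re-merge them.
  The number of alternative categories $b$ then grows, and because the
  formula's logarithm base is $b$, many rare alternatives are down-weighted
  — the pruning study in the acceptance checks measures mean ICA drifting
  slightly *up* at 20–30% missing data rather than monotonically down.
  Interpret ICA comparisons across datasets with very different
  missing-data levels cautiously.
* Node labels are attached to nodes, not edges, so rerooting a homolog
  tree can shuffle support near the old root — a general limitation of the
  newick support convention.
* The duplication counter is a counting method: it needs no dated trees,
  but it underestimates duplications relative to birth–death
  reconciliation, especially toward the tips.
* Homology inference, alignment, tree estimation, spurious-tip trimming
  and species-tree estimation are upstream of this package and out of
  scope; it consumes their newick output.
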