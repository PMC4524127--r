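# Independent brute-force oracles used to check the package's set algebra
# and node mapping. These deliberately share no code path with the
# implementation: bipartitions come from ape::prop.part, subset/intersection
# tests from setdiff/intersect, and the mapping is an exhaustive loop over
# every (homolog bipartition, species node) pair.

# all rooted bipartitions whose taxa are drawn from `taxa` (sets may be
# partial): each taxon is in the ingroup, the outgroup, or absent
enumerate_rooted_biparts <- function(taxa) {
  n <- length(taxa)
  out <- list()
  assign_next <- expand.grid(rep(list(c("in", "out", "off")), n),
                             stringsAsFactors = FALSE)
  for (r in seq_len(nrow(assign_next))) {
    a <- unlist(assign_next[r, ])
    ing <- taxa[a == "in"]; outg <- taxa[a == "out"]
    if (length(ing) >= 2 && length(outg) >= 1)
      out[[length(out) + 1L]] <- list(ingroup = ing, outgroup = outg)
  }
  out
}

naive_concordant <- function(h, s) {
  length(setdiff(h$ingroup, s$ingroup)) == 0 &&
    length(setdiff(h$outgroup, s$outgroup)) == 0
}

naive_conflicting <- function(h, s) {
  length(intersect(h$ingroup, s$ingroup)) > 0 &&
    length(intersect(h$ingroup, s$outgroup)) > 0 &&
    length(intersect(s$ingroup, h$outgroup)) > 0
}

# rooted bipartitions of a tree via ape::prop.part (root excluded),
# gene copies collapsed to taxon names
oracle_biparts <- function(tree, delimiter = "@") {
  pp <- ape::prop.part(tree)
  ntip <- length(tree$tip.label)
  taxa_all <- unique(taxon_name(tree$tip.label, delimiter))
  sup <- node_support(tree)
  out <- list()
  for (i in seq_along(pp)) {
    if (i == 1L) next  # root clade
    ing <- sort(unique(taxon_name(tree$tip.label[pp[[i]]], delimiter)))
    outg <- sort(setdiff(taxa_all, ing))
    if (length(ing) >= 2 && length(outg) >= 1)
      out[[length(out) + 1L]] <- list(ingroup = ing, outgroup = outg,
                                      support = sup[i])
  }
  out
}

# depth of every node counted by climbing parent pointers one at a time
oracle_depths <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  parent <- rep(NA_integer_, n)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  vapply(seq_len(n), function(v) {
    d <- 0L
    while (!is.na(parent[v])) { v <- parent[v]; d <- d + 1L }
    d
  }, integer(1))
}

# species nodes as plain lists keyed by their ingroup string
oracle_species_nodes <- function(tree, delimiter = "@") {
  pp <- ape::prop.part(tree)
  ntip <- length(tree$tip.label)
  taxa_all <- sort(unique(taxon_name(tree$tip.label, delimiter)))
  depths <- oracle_depths(tree)
  out <- list()
  for (i in seq_along(pp)) {
    if (i == 1L) next
    ing <- sort(unique(taxon_name(tree$tip.label[pp[[i]]], delimiter)))
    out[[length(out) + 1L]] <- list(
      ingroup = ing, outgroup = sort(setdiff(taxa_all, ing)),
      depth = depths[ntip + i],
      in_str = paste(ing, collapse = ","))
  }
  out
}

# exhaustive per-node concordant/conflicting/grey homolog counts: every
# (bipartition, species node) pair is evaluated with the naive set tests;
# the shallowest-mapping rule is applied by scanning all concordant nodes
oracle_map <- function(species_tree, gene_trees, min_support = 0,
                       delimiter = "@") {
  sp <- oracle_species_nodes(species_tree, delimiter)
  nodes <- vapply(sp, `[[`, character(1), "in_str")
  tally <- data.frame(in_str = nodes,
                      n_concordant = 0L, n_conflicting = 0L, n_grey = 0L,
                      stringsAsFactors = FALSE)
  for (g in gene_trees) {
    bips <- oracle_biparts(g, delimiter)
    conc_nodes_pass <- integer(); confl_nodes_pass <- integer()
    conc_nodes_fail <- integer(); confl_nodes_fail <- integer()
    for (b in bips) {
      pass <- is.na(b$support) || b$support >= min_support
      conc <- which(vapply(sp, function(s) naive_concordant(b, s), logical(1)))
      mapped <- integer()
      if (length(conc)) {
        dd <- vapply(sp[conc], `[[`, integer(1), "depth")
        sz <- vapply(sp[conc], function(s) length(s$ingroup), integer(1))
        ky <- vapply(sp[conc], `[[`, character(1), "in_str")
        mapped <- conc[order(-dd, sz, ky)][1L]
      }
      confl <- which(vapply(sp, function(s) naive_conflicting(b, s), logical(1)))
      if (pass) {
        conc_nodes_pass <- c(conc_nodes_pass, mapped)
        confl_nodes_pass <- c(confl_nodes_pass, confl)
      } else {
        conc_nodes_fail <- c(conc_nodes_fail, mapped)
        confl_nodes_fail <- c(confl_nodes_fail, confl)
      }
    }
    inf_pass <- union(conc_nodes_pass, confl_nodes_pass)
    inf_fail <- union(conc_nodes_fail, confl_nodes_fail)
    tally$n_concordant[unique(conc_nodes_pass)] <-
      tally$n_concordant[unique(conc_nodes_pass)] + 1L
    tally$n_conflicting[unique(confl_nodes_pass)] <-
      tally$n_conflicting[unique(confl_nodes_pass)] + 1L
    grey <- setdiff(inf_fail, inf_pass)
    tally$n_grey[grey] <- tally$n_grey[grey] + 1L
  }
  tally
}

# induced-subtree oracle: the pruned tree must reproduce the original's
# patristic distances restricted to the retained tips
expect_induced_subtree <- function(pruned, original) {
  keep <- pruned$tip.label
  d0 <- ape::cophenetic.phylo(original)[keep, keep]
  d1 <- ape::cophenetic.phylo(pruned)[keep, keep]
  expect_equal(d1, d0, tolerance = 1e-9)
}
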