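# Deterministic generator of synthetic homolog-tree sets with planted
# conflict (NNI at chosen species nodes), planted gene duplications, planted
# support values and random missingness, together with a ground-truth ledger
# that every analysis module can be checked against.

#' Specification for a synthetic homolog-tree fixture
#'
#' @param n_taxa number of species (tips of the simulated species tree).
#' @param n_homologs number of homolog trees to emit.
#' @param conflict_rate fraction of homologs NNI-perturbed at one of
#'   `conflict_nodes` (round-robin); each perturbed homolog then conflicts
#'   with the species tree at exactly that node and is concordant elsewhere.
#' @param conflict_nodes species node ids (preorder, 0-based; see
#'   [species_bipartitions()]) at which to plant conflict; default: the
#'   first internal non-root node.
#' @param dup_plan data frame (or list of pairs) with columns `node_id`,
#'   `n_events`: how many homologs receive a planted duplication of that
#'   species node's clade. Each event goes to a distinct homolog that
#'   carries no planted conflict.
#' @param support_concordant,support_conflicting percent ranges
#'   `c(low, high)` from which supports are drawn for concordant edges and
#'   for the planted conflicting edge, respectively. Defaults give
#'   concordant edges high support and conflicting edges a wide spread so
#'   bootstrap filters bite.
#' @param missing_fraction fraction of tips randomly pruned from each
#'   homolog (`[0, 1)`); the ledger is exact only at 0.
#' @param seed RNG seed; the whole fixture is reproducible from it.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_taxa = 10, n_homologs = 100, conflict_rate = 0,
                         conflict_nodes = NULL, dup_plan = NULL,
                         support_concordant = c(70, 100),
                         support_conflicting = c(20, 95),
                         missing_fraction = 0, seed = 1) {
  stopifnot(n_taxa >= 4, n_homologs >= 1,
            conflict_rate >= 0, conflict_rate <= 1,
            missing_fraction >= 0, missing_fraction < 1,
            length(support_concordant) == 2, length(support_conflicting) == 2)
  if (!is.null(dup_plan)) {
    if (!is.data.frame(dup_plan))
      dup_plan <- do.call(rbind, lapply(dup_plan, function(x)
        data.frame(node_id = x[[1]], n_events = x[[2]])))
    stopifnot(all(c("node_id", "n_events") %in% names(dup_plan)))
  }
  structure(list(n_taxa = as.integer(n_taxa),
                 n_homologs = as.integer(n_homologs),
                 conflict_rate = conflict_rate,
                 conflict_nodes = conflict_nodes, dup_plan = dup_plan,
                 support_concordant = support_concordant,
                 support_conflicting = support_conflicting,
                 missing_fraction = missing_fraction, seed = as.integer(seed)),
            class = "fixture_spec")
}

# swap one child of `node` with one sibling of `node` (a nearest-neighbour
# interchange across the edge above `node`); deterministic choice: the
# node's first child and first sibling in the edge matrix
.nni_at <- function(tree, node) {
  parent <- .parent_vec(tree)
  p <- parent[node]
  if (is.na(p)) stop("cannot NNI at the root")
  ch <- .children_list(tree)
  kids <- ch[[node]]
  sibs <- setdiff(ch[[p]], node)
  if (!length(kids) || !length(sibs)) stop("node is not NNI-eligible")
  swap_child <- kids[1L]; sib <- sibs[1L]
  e1 <- which(tree$edge[, 1L] == node & tree$edge[, 2L] == swap_child)
  e2 <- which(tree$edge[, 1L] == p & tree$edge[, 2L] == sib)
  tree$edge[e1, 2L] <- sib
  tree$edge[e2, 2L] <- swap_child
  attr(tree, "order") <- NULL
  tree <- ape::reorder.phylo(tree, "cladewise")
  ape::read.tree(text = ape::write.tree(tree))
}

# duplicate the subtree whose clade taxa equal `target_taxa`: the clade is
# replaced by a cherry of two copies, the second with fresh copy labels
.plant_duplication <- function(tree, target_taxa, delimiter = "@") {
  clade <- .clade_taxa(tree, delimiter)
  ntip <- length(tree$tip.label)
  node <- NULL
  for (v in (ntip + 1L):(ntip + tree$Nnode)) {
    if (length(clade[[v]]) == length(target_taxa) &&
        setequal(clade[[v]], target_taxa)) { node <- v; break }
  }
  if (is.null(node)) stop("no node with the target clade found")
  sub <- ape::extract.clade(tree, node)
  sub$tip.label <- paste0(taxon_name(sub$tip.label, delimiter), delimiter, "2")
  sub$root.edge <- if (is.null(sub$edge.length)) NULL else
    max(ape::node.depth.edgelength(sub)) * 0.1 + 1e-8
  pe <- which(tree$edge[, 2L] == node)
  pos <- if (is.null(tree$edge.length)) 0 else tree$edge.length[pe] / 2
  ape::bind.tree(tree, sub, where = node, position = pos)
}

#' Generate a synthetic homolog-tree fixture with ground truth
#'
#' Simulates a pure-birth species tree, then emits `n_homologs` homolog
#' trees that are copies of it (tips relabelled `taxon@1`), NNI-perturbs a
#' chosen fraction at the planted conflict nodes, plants gene duplications
#' per `dup_plan` by duplicating the target clade into a cherry of two
#' copies, draws bootstrap supports from the configured ranges (the planted
#' conflicting edge from the "conflicting" range, all others from the
#' "concordant" range), and optionally prunes random tips. A ledger records
#' the planted per-node concordant/conflicting/grey counts, the expected
#' alternative groups, ICA values, and duplication placements, all stated
#' for a bootstrap filter of 0; the ledger is exact when
#' `missing_fraction = 0`.
#'
#' @param spec a [fixture_spec()].
#' @return list of class `homolog_fixture`: `species_tree`, `gene_trees`
#'   (named list), `ledger` (list: `node_counts`, `alternatives`, `dups`,
#'   `exact`), and the `spec`.
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  species <- sim_pure_birth(spec$n_taxa)
  sb <- species_bipartitions(species)
  sn <- sb[!sb$is_root, , drop = FALSE]
  eligible <- sn$node_id
  conflict_nodes <- spec$conflict_nodes
  if (is.null(conflict_nodes)) conflict_nodes <- eligible[1L]
  if (!all(conflict_nodes %in% eligible))
    stop("conflict_nodes must be internal non-root species node ids")

  n_conf <- round(spec$conflict_rate * spec$n_homologs)
  conf_idx <- seq_len(n_conf)
  conf_node <- if (n_conf)
    conflict_nodes[(conf_idx - 1L) %% length(conflict_nodes) + 1L] else integer()

  dup_plan <- spec$dup_plan
  n_dup <- if (is.null(dup_plan)) 0L else sum(dup_plan$n_events)
  if (n_conf + n_dup > spec$n_homologs)
    stop("dup_plan and conflict_rate together need more homologs than n_homologs")
  if (n_dup) {
    if (!all(dup_plan$node_id %in% sb$node_id))
      stop("dup_plan node ids must be species node ids")
    dup_taxa_n <- vapply(dup_plan$node_id, function(id)
      length(sb$ingroup[[match(id, sb$node_id)]]), integer(1))
    if (any(dup_taxa_n < 2L))
      stop("dup_plan targets a node with fewer than 2 descendant taxa")
  }
  dup_idx <- if (n_dup) spec$n_homologs - n_dup + seq_len(n_dup) else integer()
  dup_node <- if (n_dup) rep(dup_plan$node_id, dup_plan$n_events) else integer()

  node_of <- function(id) sb$node[[match(id, sb$node_id)]]
  taxa_of <- function(id) sb$ingroup[[match(id, sb$node_id)]]

  draw_support <- function(n, range) round(stats::runif(n, range[1], range[2]), 1)

  genes <- vector("list", spec$n_homologs)
  for (i in seq_len(spec$n_homologs)) {
    g <- species
    g$tip.label <- paste0(g$tip.label, "@1")
    conflicted_at <- NA_integer_
    if (i %in% conf_idx) {
      conflicted_at <- conf_node[i]
      # only tip labels differ from the species tree, so its node numbers
      # are still valid in the copy
      g <- .nni_at(g, node_of(conflicted_at))
    }
    if (i %in% dup_idx) {
      g <- .plant_duplication(g, taxa_of(dup_node[match(i, dup_idx)]))
    }
    # supports: concordant range everywhere, conflicting range on the
    # perturbed edge (identified by its clade taxon set)
    ntip <- length(g$tip.label)
    lab <- draw_support(g$Nnode, spec$support_concordant)
    if (!is.na(conflicted_at)) {
      cl <- .clade_taxa(g)
      x_id <- conflicted_at
      kids <- .children_list(species)[[node_of(x_id)]]
      sibs <- setdiff(.children_list(species)[[.parent_vec(species)[node_of(x_id)]]],
                      node_of(x_id))
      sp_clade <- .clade_taxa(species)
      new_clade <- sort(unique(c(
        unlist(sp_clade[setdiff(kids, kids[1L])]), sp_clade[[sibs[1L]]])))
      for (v in (ntip + 1L):(ntip + g$Nnode)) {
        if (length(cl[[v]]) == length(new_clade) &&
            setequal(cl[[v]], new_clade)) {
          lab[v - ntip] <- draw_support(1L, spec$support_conflicting)
          break
        }
      }
    }
    g$node.label <- format(lab, trim = TRUE)
    if (spec$missing_fraction > 0) {
      keep_try <- prune_random(g, spec$missing_fraction)
      g <- keep_try
    }
    genes[[i]] <- g
  }
  names(genes) <- sprintf("h%04d", seq_len(spec$n_homologs))

  # ground-truth ledger (bootstrap filter 0)
  n_conf_at <- table(factor(conf_node, levels = sn$node_id))
  node_counts <- data.frame(
    node_id = sn$node_id,
    n_concordant = spec$n_homologs - as.integer(n_conf_at),
    n_conflicting = as.integer(n_conf_at),
    n_grey = 0L)
  node_counts$ica <- mapply(function(nc, nf)
    compute_ica(nc, if (nf > 0) nf else integer()),
    node_counts$n_concordant, node_counts$n_conflicting)
  alternatives <- if (n_conf) data.frame(
    node_id = as.integer(names(n_conf_at))[as.integer(n_conf_at) > 0],
    n_groups = 1L,
    n_homologs = as.integer(n_conf_at)[as.integer(n_conf_at) > 0]) else
      data.frame(node_id = integer(), n_groups = integer(),
                 n_homologs = integer())
  dups <- if (n_dup) {
    agg <- table(factor(dup_node, levels = unique(dup_node)))
    data.frame(node_id = as.integer(names(agg)),
               n_events = as.integer(agg), n_homologs = as.integer(agg))
  } else data.frame(node_id = integer(), n_events = integer(),
                    n_homologs = integer())
  res <- list(species_tree = species, gene_trees = genes,
              ledger = list(node_counts = node_counts,
                            alternatives = alternatives, dups = dups,
                            exact = spec$missing_fraction == 0),
              spec = spec)
  class(res) <- "homolog_fixture"
  res
}

#' @export
print.homolog_fixture <- function(x, ...) {
  cat(sprintf("synthetic fixture: %d taxa, %d homologs, %d with planted conflict, %d planted duplications (seed %d)\n",
              x$spec$n_taxa, x$spec$n_homologs,
              round(x$spec$conflict_rate * x$spec$n_homologs),
              if (is.null(x$spec$dup_plan)) 0L else sum(x$spec$dup_plan$n_events),
              x$spec$seed))
  invisible(x)
}

#' Write a fixture to disk
#'
#' Emits the species tree, the homolog trees (one newick per line) and the
#' ground-truth ledger tables as TSV.
#'
#' @param fixture a `homolog_fixture` from [generate_fixture()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "homolog_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "species.tre")
  ape::write.tree(fixture$species_tree, p1)
  p2 <- file.path(dir, "homologs.tre")
  writeLines(vapply(fixture$gene_trees, ape::write.tree, character(1)), p2)
  p3 <- file.path(dir, "ledger.node_counts.tsv")
  utils::write.table(fixture$ledger$node_counts, p3, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  p4 <- file.path(dir, "ledger.dups.tsv")
  utils::write.table(fixture$ledger$dups, p4, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(p1, p2, p3, p4))
}
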