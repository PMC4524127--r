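# Null-distribution machinery: pure-birth species trees, multispecies
# coalescent (MSC) gene-tree simulation on an ultrametric species tree in
# coalescent units, random taxon pruning, and per-node ranked
# alternative-frequency curves.

# build a phylo from a binary merge history: tips 1..n, merge k creates
# lineage n+k at the given age; the last merge is the root
.build_phylo_from_merges <- function(tip_labels, a, b, age) {
  n <- length(tip_labels)
  m <- length(a)
  stopifnot(m == n - 1L)
  ch1 <- a; ch2 <- b
  node_age <- c(rep(0, n), age)
  root <- n + m
  # lay edges down in DFS order from the root (original merge ids), then
  # renumber internal nodes preorder so ape gets a cladewise tree
  edge <- matrix(0L, nrow = 2L * m, ncol = 2L)
  elen <- numeric(2L * m)
  # stack of pending edges (parent, child); children pushed in reverse so
  # each clade's edges are laid down contiguously (preorder / cladewise)
  estack <- matrix(c(root, ch2[m], root, ch1[m]), ncol = 2L, byrow = TRUE)
  erow <- 0L
  while (nrow(estack)) {
    p <- estack[nrow(estack), 1L]; cur <- estack[nrow(estack), 2L]
    estack <- estack[-nrow(estack), , drop = FALSE]
    erow <- erow + 1L
    edge[erow, 1L] <- p
    edge[erow, 2L] <- cur
    elen[erow] <- node_age[p] - node_age[cur]
    if (cur > n) {
      k <- cur - n
      estack <- rbind(estack, c(cur, ch2[k]), c(cur, ch1[k]))
    }
  }
  newid <- integer(n + m)
  newid[seq_len(n)] <- seq_len(n)
  newid[root] <- n + 1L
  nxt <- n + 2L
  for (i in seq_len(2L * m)) {
    ch <- edge[i, 2L]
    if (ch > n && newid[ch] == 0L) {
      newid[ch] <- nxt
      nxt <- nxt + 1L
    }
  }
  edge[, 1L] <- newid[edge[, 1L]]
  edge[, 2L] <- newid[edge[, 2L]]
  tr <- list(edge = edge, edge.length = elen, tip.label = tip_labels,
             Nnode = m)
  class(tr) <- "phylo"
  attr(tr, "order") <- "cladewise"
  tr
}

#' Simulate a pure-birth (Yule) species tree
#'
#' Grows a tree under a constant-rate pure-birth process until `n_taxa`
#' lineages exist, then extends all pendant branches by a final exponential
#' waiting time at the full rate, so the expected root height with unit
#' birth rate is `sum(1/k, k = 2..n_taxa)`. The result is ultrametric with
#' tips `t1..tn`.
#'
#' @param n_taxa number of tips (>= 2).
#' @param seed optional RNG seed for reproducibility.
#' @param birth birth rate (default 1).
#' @return an ultrametric `phylo`.
#' @export
sim_pure_birth <- function(n_taxa, seed = NULL, birth = 1) {
  if (n_taxa < 2L) stop("n_taxa must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  # lineage bookkeeping: birth time, children (0 = none yet), split time
  max_n <- 2L * n_taxa
  tb <- numeric(max_n); ts <- rep(NA_real_, max_n)
  c1 <- integer(max_n); c2 <- integer(max_n)
  alive <- c(1L, 2L)
  n_lin <- 2L
  last_id <- 2L
  t <- 0
  while (n_lin < n_taxa) {
    t <- t + stats::rexp(1, n_lin * birth)
    j <- alive[sample.int(length(alive), 1L)]
    ts[j] <- t
    a <- last_id + 1L; b <- last_id + 2L
    last_id <- b
    if (b > length(tb)) {
      tb <- c(tb, numeric(b)); ts <- c(ts, rep(NA_real_, b))
      c1 <- c(c1, integer(b)); c2 <- c(c2, integer(b))
    }
    tb[a] <- t; tb[b] <- t
    c1[j] <- a; c2[j] <- b
    alive <- c(setdiff(alive, j), a, b)
    n_lin <- n_lin + 1L
  }
  t_end <- t + stats::rexp(1, n_taxa * birth)
  tips <- sort(alive)
  lab <- stats::setNames(paste0("t", seq_along(tips)), tips)
  nwk <- function(j) {
    if (c1[j] == 0L) sprintf("%s:%.12g", lab[[as.character(j)]], t_end - tb[j])
    else sprintf("(%s,%s):%.12g", nwk(c1[j]), nwk(c2[j]), ts[j] - tb[j])
  }
  txt <- sprintf("(%s,%s);", nwk(1L), nwk(2L))
  ape::read.tree(text = txt)
}

#' Rescale an ultrametric tree to a target root height
#'
#' Multiplies all branch lengths by `target / height`, so the root-to-tip
#' distance becomes `target` exactly. Used to place a species tree on a
#' chosen coalescent-unit depth before simulation.
#'
#' @param tree ultrametric `phylo` with branch lengths.
#' @param target positive root height after rescaling.
#' @param tol ultrametricity tolerance (relative), default `1e-6`.
#' @return the rescaled `phylo`.
#' @export
rescale_root_height <- function(tree, target, tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"), target > 0)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (!ape::is.ultrametric(tree, tol = tol, option = 2))
    stop("tree is not ultrametric within tolerance")
  h <- max(ape::node.depth.edgelength(tree))
  if (h <= 0) stop("tree has zero height")
  tree$edge.length <- tree$edge.length * (target / h)
  tree
}

#' Simulate gene trees under the multispecies coalescent
#'
#' For each gene, one lineage starts at every species tip; within each
#' species-tree branch, lineages coalesce with exponential waiting times at
#' rate `choose(k, 2)` per coalescent unit, and lineages that have not
#' coalesced by the root continue coalescing above it at the same rate
#' (standard Kingman continuation). Branch lengths of the species tree are
#' interpreted directly as coalescent units. Gene trees are rooted and
#' ultrametric in coalescent units, with the same tip labels as the species
#' tree.
#'
#' @param species_tree ultrametric `phylo` with branch lengths in coalescent
#'   units.
#' @param n_genes number of gene trees to simulate.
#' @param seed optional RNG seed.
#' @param tol ultrametricity tolerance.
#' @return list of `phylo` gene trees (class `multiPhylo`), named `g1...`.
#' @export
sim_msc <- function(species_tree, n_genes, seed = NULL, tol = 1e-6) {
  stopifnot(inherits(species_tree, "phylo"), n_genes >= 1L)
  if (!ape::is.ultrametric(species_tree, tol = tol, option = 2))
    stop("species tree must be ultrametric (coalescent units)")
  if (!is.null(seed)) set.seed(seed)
  ntip <- length(species_tree$tip.label)
  nnode <- species_tree$Nnode
  depth <- ape::node.depth.edgelength(species_tree)
  node_age <- max(depth) - depth
  node_age[node_age < tol] <- 0
  parent <- .parent_vec(species_tree)
  # children precede parents: increasing age, ties broken by topological
  # depth (deeper first) so zero-length internal branches cannot reorder a
  # child after its parent
  ord <- order(node_age, -.node_depths(species_tree))
  ch <- .children_list(species_tree)
  root <- .root_node(species_tree)

  one_gene <- function() {
    max_m <- ntip - 1L
    ma <- integer(max_m); mb <- integer(max_m); mage <- numeric(max_m)
    mcount <- 0L
    lin <- vector("list", ntip + nnode)
    for (i in seq_len(ntip)) lin[[i]] <- i
    for (node in ord) {
      L <- if (node <= ntip) lin[[node]]
      else unlist(lin[ch[[node]]], use.names = FALSE)
      t0 <- node_age[node]
      t1 <- if (is.na(parent[node])) Inf else node_age[parent[node]]
      k <- length(L)
      t <- t0
      while (k > 1L) {
        t <- t + stats::rexp(1, k * (k - 1) / 2)
        if (t >= t1) break
        pick <- sample.int(k, 2L)
        mcount <- mcount + 1L
        ma[mcount] <- L[pick[1L]]; mb[mcount] <- L[pick[2L]]
        mage[mcount] <- t
        L[pick[1L]] <- ntip + mcount
        L <- L[-pick[2L]]
        k <- k - 1L
      }
      lin[[node]] <- L
    }
    .build_phylo_from_merges(species_tree$tip.label,
                             ma[seq_len(mcount)], mb[seq_len(mcount)],
                             mage[seq_len(mcount)])
  }
  out <- lapply(seq_len(n_genes), function(i) one_gene())
  names(out) <- paste0("g", seq_len(n_genes))
  class(out) <- "multiPhylo"
  out
}

#' Randomly prune tips from a tree
#'
#' Removes `round(fraction * n_tips)` uniformly chosen tips and suppresses
#' the resulting degree-2 nodes, summing branch lengths, so the induced
#' topology is the restriction of the original to the retained tips.
#'
#' @param tree a `phylo`.
#' @param fraction fraction of tips to remove, in `[0, 1)`.
#' @param seed optional RNG seed.
#' @return the pruned `phylo`.
#' @export
prune_random <- function(tree, fraction, seed = NULL) {
  stopifnot(fraction >= 0, fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  ntip <- length(tree$tip.label)
  n_drop <- round(fraction * ntip)
  if (n_drop == 0L) return(tree)
  if (ntip - n_drop < 3L)
    stop("pruning would leave fewer than 3 tips")
  drop <- sample.int(ntip, n_drop)
  ape::drop.tip(tree, drop)
}

#' Null distributions of conflict under the multispecies coalescent
#'
#' For each requested root height, rescales the species tree to that height
#' (coalescent units), simulates `n_genes` gene trees under the
#' multispecies coalescent, maps them back onto the species-tree topology
#' ([map_conflicts()], no bootstrap filter: simulated trees carry no
#' support), and records per species node the proportion of gene trees
#' supporting each ranked conflicting alternative, sorted from largest to
#' smallest. The pointwise min-max band across heights is reported as a
#' descriptive envelope for judging whether an empirical conflict profile is
#' compatible with incomplete lineage sorting alone.
#'
#' @param species_tree ultrametric `phylo` in coalescent units.
#' @param root_heights numeric vector of root heights (e.g. `c(10, 20, 30)`:
#'   deep coalescence ranges from frequent to rare).
#' @param n_genes gene trees per height.
#' @param seed optional RNG seed (offset per height for independence).
#' @param delimiter taxon delimiter.
#' @return object of class `conflict_null`: `curves` (data frame: `height`,
#'   `node_id`, `rank`, `n_homologs`, `prop`; rank 0 rows carry the
#'   concordant proportion), `envelope` (per `node_id` and `rank`: min/max
#'   proportion across heights), `heights`, `n_genes`.
#' @export
conflict_null <- function(species_tree, root_heights = c(10, 20, 30),
                          n_genes = 1000, seed = NULL, delimiter = "@") {
  curves <- list()
  for (i in seq_along(root_heights)) {
    h <- root_heights[i]
    st <- rescale_root_height(species_tree, h)
    genes <- sim_msc(st, n_genes,
                     seed = if (is.null(seed)) NULL else seed + i - 1L)
    nc <- map_conflicts(species_tree, genes, min_support = 0,
                        delimiter = delimiter)
    for (r in seq_len(nrow(nc$summary))) {
      nid <- nc$summary$node_id[r]
      galt <- nc$alternatives[[as.character(nid)]]
      curves[[length(curves) + 1L]] <- data.frame(
        height = h, node_id = nid,
        rank = c(0L, galt$rank),
        n_homologs = c(nc$summary$n_concordant[r], galt$n_homologs),
        prop = c(nc$summary$n_concordant[r], galt$n_homologs) / n_genes,
        stringsAsFactors = FALSE)
    }
  }
  curves <- do.call(rbind, curves)
  env <- stats::aggregate(prop ~ node_id + rank, data = curves,
                          FUN = function(x) c(min = min(x), max = max(x)))
  env <- data.frame(node_id = env$node_id, rank = env$rank,
                    prop_min = env$prop[, "min"], prop_max = env$prop[, "max"])
  res <- list(curves = curves, envelope = env, heights = root_heights,
              n_genes = n_genes)
  class(res) <- "conflict_null"
  res
}

#' @export
print.conflict_null <- function(x, ...) {
  cat(sprintf("coalescent null: %d genes per height at heights %s; %d node curves\n",
              x$n_genes, paste(x$heights, collapse = ", "),
              length(unique(x$curves$node_id))))
  invisible(x)
}

#' Write null-distribution curves to disk
#'
#' Emits one `"<prefix>.null.node<k>.tsv"` per species node with columns
#' `height`, `rank`, `n_homologs`, `prop`.
#'
#' @param x a `conflict_null` object.
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
write_null_outputs <- function(x, prefix) {
  stopifnot(inherits(x, "conflict_null"))
  paths <- character()
  for (nid in unique(x$curves$node_id)) {
    sub <- x$curves[x$curves$node_id == nid,
                    c("height", "rank", "n_homologs", "prop")]
    f <- sprintf("%s.null.node%d.tsv", prefix, nid)
    utils::write.table(sub, f, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, f)
  }
  invisible(paths)
}
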