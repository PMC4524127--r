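# Mapping homolog bipartitions onto a species tree: concordance, conflict,
# grouping of conflicting alternatives, per-node summaries and pie
# proportions, and internode certainty (ICA).

#' Rooted bipartitions of a species tree
#'
#' Numbers the internal nodes of a rooted species tree deterministically
#' (preorder from the root, 0-based; the root is node 0) and returns each
#' node's rooted bipartition. The root carries no non-trivial bipartition
#' (`is_root` flags it); all other internal nodes partition the species taxa
#' into the clade toward the tips (ingroup) and the rest (outgroup).
#'
#' @param tree rooted species `phylo` tree.
#' @param delimiter taxon delimiter for tip labels, see [taxon_name()].
#' @return data frame with columns `node_id`, `node` (ape number), `depth`
#'   (edges from root), `is_root`, `n_in`, `in_str` plus list-columns
#'   `ingroup`, `outgroup`.
#' @export
species_bipartitions <- function(tree, delimiter = "@") {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  clade <- .clade_taxa(tree, delimiter)
  depths <- .node_depths(tree)
  ids <- .preorder_ids(tree)
  nodes <- as.integer(names(ids))
  full <- clade[[.root_node(tree)]]
  df <- data.frame(node_id = as.integer(ids), node = nodes,
                   depth = depths[nodes],
                   is_root = nodes == .root_node(tree),
                   stringsAsFactors = FALSE)
  df$ingroup <- clade[nodes]
  df$outgroup <- lapply(clade[nodes], function(x) setdiff(full, x))
  df$n_in <- lengths(df$ingroup)
  df$in_str <- vapply(df$ingroup, paste, character(1), collapse = ",")
  df[order(df$node_id), , drop = FALSE]
}

#' Concordance of a homolog bipartition with a species bipartition
#'
#' A homolog bipartition `h` is concordant with a species bipartition `s`
#' when the ingroup of `s` contains all of the ingroup of `h` and the
#' outgroup of `s` contains all of the outgroup of `h`. Taxon sets may
#' differ between the two (partial overlap is the norm for homolog trees).
#'
#' @param h,s [rooted_bipartition()] objects, or plain lists with `ingroup`
#'   and `outgroup` character vectors.
#' @return logical.
#' @export
is_concordant <- function(h, s) {
  all(h$ingroup %in% s$ingroup) && all(h$outgroup %in% s$outgroup)
}

#' Conflict of a homolog bipartition with a species bipartition
#'
#' `h` conflicts with `s` when all three of these intersections are
#' non-empty: ingroup(`h`) with ingroup(`s`); ingroup(`h`) with
#' outgroup(`s`); and ingroup(`s`) with outgroup(`h`). A pair that is
#' neither concordant nor conflicting is uninformative for `s`. Concordance
#' and conflict are mutually exclusive.
#'
#' @inheritParams is_concordant
#' @return logical.
#' @export
is_conflicting <- function(h, s) {
  any(h$ingroup %in% s$ingroup) &&
    any(h$ingroup %in% s$outgroup) &&
    any(s$ingroup %in% h$outgroup)
}

#' Internode certainty (ICA) from category counts
#'
#' Computes `1 + sum P(X_n) log_b P(X_n)` over the focal bipartition and its
#' conflicting alternatives, where `b` is the number of categories with
#' positive counts (including the focal one) and `P(X_n)` are the
#' proportional frequencies. With a single category (`b = 1`) the value is
#' defined as 1 (no conflict); equal frequencies give 0 (maximal conflict).
#'
#' @param n_concordant count of homologs supporting the focal bipartition.
#' @param alternative_counts counts of homologs supporting each grouped
#'   conflicting alternative.
#' @return ICA in `[0, 1]`.
#' @examples
#' compute_ica(100)            # 1
#' compute_ica(50, 50)         # 0
#' compute_ica(60, c(30, 10))  # ~0.183
#' @export
compute_ica <- function(n_concordant, alternative_counts = integer()) {
  counts <- c(n_concordant, alternative_counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  pos <- counts[counts > 0]
  if (!length(pos)) stop("all counts are zero: node is uninformed")
  b <- length(pos)
  if (b == 1L) return(1)
  p <- pos / sum(pos)
  1 + sum(p * log(p, base = b))
}

#' Group conflicting bipartitions into alternative statements
#'
#' All-by-all grouping of the bipartitions that conflict with one species
#' node: two bipartitions make the same phylogenetic statement when one is
#' contained completely within the other (ingroup within ingroup and
#' outgroup within outgroup, in either direction), as happens under reduced
#' taxon sampling. Groups are closed greedily in descending order of
#' bipartition frequency (ties by lexicographic ingroup); a bipartition
#' compatible with several group representatives joins each, so the
#' cumulative sum of group counts may exceed the number of conflicting
#' homologs.
#'
#' @param biparts list of [rooted_bipartition()] objects (all conflicting
#'   with the same focal species bipartition).
#' @return data frame with columns `rank`, `n_homologs`, `n_biparts`,
#'   `ingroup`, `outgroup` (representative statement, semicolon-joined),
#'   sorted by `n_homologs` descending; plus attribute `members`, a list of
#'   the homolog-id sets per group.
#' @export
group_alternatives <- function(biparts) {
  if (!length(biparts)) {
    out <- data.frame(rank = integer(), n_homologs = integer(),
                      n_biparts = integer(), ingroup = character(),
                      outgroup = character(), stringsAsFactors = FALSE)
    attr(out, "members") <- list()
    return(out)
  }
  df <- data.frame(
    key = vapply(biparts, function(b) .bip_key(b$ingroup, b$outgroup), character(1)),
    hid = vapply(biparts, function(b) as.character(b$homolog_id), character(1)),
    stringsAsFactors = FALSE)
  ins <- lapply(biparts, `[[`, "ingroup")
  outs <- lapply(biparts, `[[`, "outgroup")
  ukeys <- unique(df$key)
  freq <- vapply(ukeys, function(k) sum(df$key == k), integer(1))
  first <- match(ukeys, df$key)
  in_str <- vapply(first, function(i) paste(ins[[i]], collapse = ","), character(1))
  ord <- order(-freq, in_str)
  reps_in <- list(); reps_out <- list(); members <- list()
  for (j in ord) {
    ki <- ins[[first[j]]]; ko <- outs[[first[j]]]
    hit <- FALSE
    if (length(reps_in)) {
      for (g in seq_along(reps_in)) {
        ri <- reps_in[[g]]; ro <- reps_out[[g]]
        contained <- (all(ki %in% ri) && all(ko %in% ro)) ||
          (all(ri %in% ki) && all(ro %in% ko))
        if (contained) {
          members[[g]] <- c(members[[g]], j)
          hit <- TRUE
        }
      }
    }
    if (!hit) {
      reps_in[[length(reps_in) + 1L]] <- ki
      reps_out[[length(reps_out) + 1L]] <- ko
      members[[length(members) + 1L]] <- j
    }
  }
  hids <- lapply(members, function(idx)
    sort(unique(df$hid[df$key %in% ukeys[idx]])))
  n_hom <- lengths(hids)
  rep_in <- vapply(members, function(idx)
    paste(ins[[first[idx[1L]]]], collapse = ";"), character(1))
  rep_out <- vapply(members, function(idx)
    paste(outs[[first[idx[1L]]]], collapse = ";"), character(1))
  n_bip <- vapply(members, function(idx) sum(freq[idx]), integer(1))
  o <- order(-n_hom, rep_in)
  out <- data.frame(rank = seq_along(o), n_homologs = n_hom[o],
                    n_biparts = n_bip[o], ingroup = rep_in[o],
                    outgroup = rep_out[o], stringsAsFactors = FALSE)
  attr(out, "members") <- hids[o]
  out
}

# incidence matrix of taxon sets over a fixed taxon universe
.set_matrix <- function(sets, taxa) {
  m <- matrix(0, nrow = length(sets), ncol = length(taxa),
              dimnames = list(NULL, taxa))
  for (i in seq_along(sets)) m[i, match(sets[[i]], taxa)] <- 1
  m
}

#' Map homolog trees onto a species tree as concordant or conflicting
#'
#' Decomposes each rooted homolog tree into rooted bipartitions and maps them
#' onto the species tree. A bipartition concordant with several species
#' bipartitions is mapped to the shallowest one (furthest from the root; ties
#' under polytomies broken by smallest ingroup, then lexicographic ingroup).
#' Per species node, each homolog votes at most once per category: it is
#' counted concordant if at least one of its passing bipartitions maps to
#' that node, conflicting if at least one passing bipartition conflicts with
#' the node's bipartition, and below-filter informative ("grey") if it has no
#' passing informative bipartition for the node but at least one failing
#' bipartition that would be concordant or conflicting there. Conflicting
#' passing bipartitions at each node are grouped into alternative statements
#' ([group_alternatives()]) and the node's ICA is computed from the
#' homolog-level concordant count and the grouped alternative counts.
#'
#' @param species_tree rooted species `phylo`; its taxa must cover all
#'   homolog taxa.
#' @param gene_trees list of rooted homolog `phylo` trees (names = homolog
#'   ids).
#' @param min_support bootstrap filter in percent (edges with support below
#'   it are ignored); default 50.
#' @param delimiter taxon delimiter for tip labels.
#' @param missing_support_fails policy for edges lacking support, see
#'   [decompose_bipartitions()].
#' @return object of class `node_conflict`: list with elements `summary`
#'   (data frame: `node_id`, `n_concordant`, `n_conflicting`, `n_grey`,
#'   `n_informative`, `ica`, `alt_exceeds_focal`, pie proportions),
#'   `alternatives` (list of [group_alternatives()] tables keyed by node id),
#'   `membership` (per node: concordant / conflicting / grey homolog id
#'   sets), `node_key`, `species_tree`, and the parameters used.
#' @export
map_conflicts <- function(species_tree, gene_trees, min_support = 50,
                          delimiter = "@", missing_support_fails = FALSE) {
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  stopifnot(length(gene_trees) >= 1L)
  ids <- names(gene_trees)
  if (is.null(ids)) ids <- sprintf("h%04d", seq_along(gene_trees))
  sb <- species_bipartitions(species_tree, delimiter)
  taxa <- sort(unique(taxon_name(species_tree$tip.label, delimiter)))

  gene_taxa <- lapply(gene_trees, function(t)
    unique(taxon_name(t$tip.label, delimiter)))
  missing <- sort(unique(unlist(lapply(gene_taxa, setdiff, y = taxa))))
  if (length(missing))
    stop("homolog taxa absent from the species tree: ",
         paste(missing, collapse = ", "), call. = FALSE)

  bip <- do.call(rbind, mapply(function(t, id)
    .decompose_df(t, delimiter, min_support, missing_support_fails, id),
    gene_trees, ids, SIMPLIFY = FALSE))

  sn <- sb[!sb$is_root, , drop = FALSE]
  n_nodes <- nrow(sn)
  empty_alt <- group_alternatives(list())

  if (is.null(bip) || !nrow(bip)) {
    summary <- data.frame(node_id = sn$node_id, n_concordant = 0L,
                          n_conflicting = 0L, n_grey = 0L, n_informative = 0L,
                          ica = NA_real_, alt_exceeds_focal = FALSE,
                          prop_concordant = NA_real_, prop_top_alt = NA_real_,
                          prop_other_alt = NA_real_, prop_grey = NA_real_)
    res <- list(summary = summary,
                alternatives = stats::setNames(rep(list(empty_alt), n_nodes),
                                               sn$node_id),
                membership = NULL, node_key = sb[, c("node_id", "node", "depth", "in_str")],
                species_tree = species_tree, n_homologs = length(gene_trees),
                min_support = min_support, delimiter = delimiter)
    class(res) <- "node_conflict"
    return(res)
  }

  Hin <- .set_matrix(bip$ingroup, taxa)
  Hout <- .set_matrix(bip$outgroup, taxa)
  Sin <- .set_matrix(sn$ingroup, taxa)
  Sout <- .set_matrix(sn$outgroup, taxa)

  # concordant: ingroup(h) subset ingroup(s) AND outgroup(h) subset outgroup(s)
  conc <- (Hin %*% t(1 - Sin) == 0) & (Hout %*% t(1 - Sout) == 0)
  # conflicting: three non-empty intersections
  confl <- (Hin %*% t(Sin) > 0) & (Hin %*% t(Sout) > 0) & (Hout %*% t(Sin) > 0)

  # shallowest mapping: deepest concordant s; ties by smallest then
  # lexicographic ingroup
  prio <- order(-sn$depth, sn$n_in, sn$in_str)
  mapped <- rep(NA_integer_, nrow(bip))
  for (j in prio) {
    hit <- which(is.na(mapped) & conc[, j])
    if (length(hit)) mapped[hit] <- j
  }

  hid <- bip$homolog_id
  all_h <- unique(hid)
  summary <- vector("list", n_nodes)
  alts <- vector("list", n_nodes)
  membership <- vector("list", n_nodes)
  for (j in seq_len(n_nodes)) {
    informative <- (!is.na(mapped) & mapped == j) | confl[, j]
    pass_inf <- informative & bip$pass
    conc_h <- unique(hid[bip$pass & !is.na(mapped) & mapped == j])
    confl_h <- unique(hid[bip$pass & confl[, j]])
    pass_inf_h <- unique(hid[pass_inf])
    grey_h <- setdiff(unique(hid[informative & !bip$pass]), pass_inf_h)
    denom_h <- unique(hid[informative])

    idx <- which(bip$pass & confl[, j])
    galt <- if (length(idx)) {
      group_alternatives(lapply(idx, function(i)
        rooted_bipartition(bip$ingroup[[i]], bip$outgroup[[i]],
                           bip$support[i], hid[i], bip$node[i])))
    } else empty_alt
    alts[[j]] <- galt

    n_conc <- length(conc_h); n_confl <- length(confl_h); n_grey <- length(grey_h)
    ica <- if (n_conc == 0L && nrow(galt) == 0L) NA_real_ else
      compute_ica(n_conc, galt$n_homologs)
    top_set <- if (nrow(galt)) attr(galt, "members")[[1L]] else character()
    # disjoint pie slices over homologs informative at any support level
    confl_only <- setdiff(confl_h, conc_h)
    top_slice <- intersect(confl_only, top_set)
    D <- length(denom_h)
    summary[[j]] <- data.frame(
      node_id = sn$node_id[j],
      n_concordant = n_conc, n_conflicting = n_confl, n_grey = n_grey,
      n_informative = D,
      ica = ica,
      alt_exceeds_focal = nrow(galt) > 0L && galt$n_homologs[1L] > n_conc,
      prop_concordant = if (D) n_conc / D else NA_real_,
      prop_top_alt = if (D) length(top_slice) / D else NA_real_,
      prop_other_alt = if (D) length(setdiff(confl_only, top_slice)) / D else NA_real_,
      prop_grey = if (D) n_grey / D else NA_real_,
      stringsAsFactors = FALSE)
    membership[[j]] <- list(concordant = sort(conc_h),
                            conflicting = sort(confl_h),
                            grey = sort(grey_h))
  }
  summary <- do.call(rbind, summary)
  names(alts) <- sn$node_id
  names(membership) <- sn$node_id
  res <- list(summary = summary, alternatives = alts, membership = membership,
              node_key = sb[, c("node_id", "node", "depth", "in_str")],
              species_tree = species_tree, n_homologs = length(gene_trees),
              min_support = min_support, delimiter = delimiter)
  class(res) <- "node_conflict"
  res
}

#' @export
print.node_conflict <- function(x, ...) {
  cat(sprintf("conflict/concordance summary: %d homologs on %d species-tree nodes (filter >= %g%%)\n",
              x$n_homologs, nrow(x$summary), x$min_support))
  print.data.frame(x$summary[, c("node_id", "n_concordant", "n_conflicting",
                                 "n_grey", "ica")], digits = 3)
  invisible(x)
}

#' Write per-node conflict summaries to disk
#'
#' Emits `"<prefix>.concord.node.tsv"` (per-node counts and ICA),
#' `"<prefix>.alternatives.node<k>.tsv"` for every node with conflicting
#' alternatives, `"<prefix>.species.nodekey.tre"` (species tree with node ids
#' as internal labels) and `"<prefix>.species.ica.tre"` (ICA values as
#' internal labels).
#'
#' @param x a `node_conflict` object from [map_conflicts()].
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
write_conflict_outputs <- function(x, prefix) {
  stopifnot(inherits(x, "node_conflict"))
  paths <- character()
  f <- paste0(prefix, ".concord.node.tsv")
  utils::write.table(x$summary, f, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, f)
  for (nid in names(x$alternatives)) {
    a <- x$alternatives[[nid]]
    if (!nrow(a)) next
    f <- sprintf("%s.alternatives.node%s.tsv", prefix, nid)
    utils::write.table(a[, c("rank", "n_homologs", "ingroup", "outgroup")],
                       f, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, f)
  }
  tr <- x$species_tree
  ids <- .preorder_ids(tr)
  ntip <- length(tr$tip.label)
  lab <- rep("", tr$Nnode)
  lab[as.integer(names(ids)) - ntip] <- as.character(ids)
  tr$node.label <- lab
  f <- paste0(prefix, ".species.nodekey.tre")
  ape::write.tree(tr, f); paths <- c(paths, f)
  ica <- rep("", tr$Nnode)
  m <- match(x$summary$node_id, as.integer(ids))
  ica[as.integer(names(ids))[m] - ntip] <-
    ifelse(is.na(x$summary$ica), "NA", sprintf("%.3f", x$summary$ica))
  tr$node.label <- ica
  f <- paste0(prefix, ".species.ica.tre")
  ape::write.tree(tr, f); paths <- c(paths, f)
  invisible(paths)
}
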