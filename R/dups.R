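# Gene-duplication detection in homolog trees by the shared-taxon criterion,
# with a local bootstrap filter, and mapping of species-tree-congruent
# duplications onto species-tree nodes.

#' Find gene-duplication nodes in a homolog tree
#'
#' Walks the homolog tree in postorder (tips to root). A node is recorded as
#' a duplication when at least two taxa each have gene copies in at least two
#' of its children's taxon sets (for a binary node: the intersection of the
#' left and right descendant taxon sets has two or more taxa). The union of
#' the descendant taxon sets is carried upward, so nested duplications are
#' each detected. A local bootstrap filter applies: the focal node and every
#' internal child must pass `min_support` (tip children carry no support and
#' are exempt). Requiring two shared taxa means the method loses power
#' toward the tips, where only one taxon may retain both copies.
#'
#' @param tree rooted homolog `phylo` tree.
#' @param delimiter taxon delimiter for tip labels, see [taxon_name()].
#' @param min_support local bootstrap filter in percent (default 50).
#' @param missing_support_fails policy for edges lacking support, see
#'   [decompose_bipartitions()].
#' @param homolog_id identifier recorded on each event.
#' @return data frame of class `duplication_events`, one row per event, with
#'   columns `homolog_id`, `node` (ape node number), `n_shared`, `support`,
#'   and list-columns `shared_taxa`, `union_taxa`.
#' @export
find_duplications <- function(tree, delimiter = "@", min_support = 50,
                              missing_support_fails = FALSE, homolog_id = "") {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  n <- ntip + tree$Nnode
  clade <- .clade_taxa(tree, delimiter)
  sup <- node_support(tree)
  ch <- .children_list(tree)
  pass <- function(node) {
    if (node <= ntip) return(TRUE)  # tips carry no support
    .passes_filter(sup[node - ntip], min_support, missing_support_fails)
  }
  rows <- list()
  for (node in (ntip + 1L):n) {
    kids <- ch[[node]]
    if (length(kids) < 2L) next
    tax <- unlist(lapply(kids, function(k) unique(clade[[k]])))
    shared <- sort(unique(tax[duplicated(tax)]))
    if (length(shared) < 2L) next
    if (!pass(node)) next
    if (!all(vapply(kids, pass, logical(1)))) next
    rows[[length(rows) + 1L]] <- list(
      node = node, shared = shared, union = clade[[node]],
      support = if (node - ntip >= 1L) sup[node - ntip] else NA_real_)
  }
  out <- data.frame(
    homolog_id = rep(homolog_id, length(rows)),
    node = vapply(rows, `[[`, integer(1), "node"),
    n_shared = vapply(rows, function(r) length(r$shared), integer(1)),
    support = vapply(rows, `[[`, numeric(1), "support"),
    stringsAsFactors = FALSE)
  out$shared_taxa <- lapply(rows, `[[`, "shared")
  out$union_taxa <- lapply(rows, `[[`, "union")
  class(out) <- c("duplication_events", "data.frame")
  out
}

#' Map duplication events onto a species tree
#'
#' Only duplications congruent with the species tree are mapped: an event
#' maps through the rooted bipartition formed by its descendant taxon-set
#' union against the remaining taxa of its homolog; if that bipartition is
#' concordant with some species bipartition the event is placed on the
#' shallowest such node. When the union covers the homolog's full taxon set
#' (no outgroup left), the event is placed on the MRCA of the union in the
#' species tree. Events that conflict with the species tree stay unmapped.
#' The MRCA of the union is also reported for every event as `mrca_node`,
#' since the two placements can differ under missing taxa.
#'
#' @param species_tree rooted species `phylo` covering all event taxa.
#' @param events a `duplication_events` data frame (rows from
#'   [find_duplications()] over one or more homologs, `rbind`-ed).
#' @param homolog_taxa named list: full taxon set of each homolog tree.
#' @param delimiter taxon delimiter for species tip labels.
#' @return list of class `duplication_map`: `events` (input plus
#'   `mapped_node` and `mrca_node` species node ids, `NA` if unmapped),
#'   `by_node` (data frame `node_id`, `n_duplications`, `n_homologs`), and
#'   `unmapped` (counts of unmapped events and distinct homologs).
#' @export
map_duplications <- function(species_tree, events, homolog_taxa,
                             delimiter = "@") {
  sb <- species_bipartitions(species_tree, delimiter)
  sn <- sb[!sb$is_root, , drop = FALSE]
  ids_by_node <- stats::setNames(sb$node_id, sb$node)
  prio <- order(-sn$depth, sn$n_in, sn$in_str)
  species_taxa <- sb$ingroup[[which(sb$is_root)]]
  tip_tax <- taxon_name(species_tree$tip.label, delimiter)

  mrca_of <- function(taxa) {
    tips <- which(tip_tax %in% taxa)
    if (!length(tips)) return(NA_integer_)
    node <- if (length(tips) == 1L)
      species_tree$edge[species_tree$edge[, 2L] == tips, 1L]
    else ape::getMRCA(species_tree, tips)
    as.integer(ids_by_node[as.character(node)])
  }

  n_ev <- nrow(events)
  mapped <- rep(NA_integer_, n_ev)
  mrca <- rep(NA_integer_, n_ev)
  for (i in seq_len(n_ev)) {
    un <- events$union_taxa[[i]]
    bad <- setdiff(un, species_taxa)
    if (length(bad))
      stop("duplication taxa absent from the species tree: ",
           paste(bad, collapse = ", "), call. = FALSE)
    mrca[i] <- mrca_of(un)
    htax <- homolog_taxa[[events$homolog_id[i]]]
    outg <- setdiff(htax, un)
    if (!length(outg)) {           # union spans the homolog: root-equivalent
      mapped[i] <- mrca[i]
      next
    }
    h <- list(ingroup = un, outgroup = outg)
    for (j in prio) {
      s <- list(ingroup = sn$ingroup[[j]], outgroup = sn$outgroup[[j]])
      if (is_concordant(h, s)) { mapped[i] <- sn$node_id[j]; break }
    }
  }
  events$mapped_node <- mapped
  events$mrca_node <- mrca
  ok <- !is.na(mapped)
  by_node <- data.frame(node_id = sb$node_id, n_duplications = 0L,
                        n_homologs = 0L)
  if (any(ok)) {
    tab <- split(events$homolog_id[ok], mapped[ok])
    idx <- match(as.integer(names(tab)), by_node$node_id)
    by_node$n_duplications[idx] <- lengths(tab)
    by_node$n_homologs[idx] <- vapply(tab, function(x) length(unique(x)),
                                      integer(1))
  }
  res <- list(events = events, by_node = by_node,
              unmapped = c(events = sum(!ok),
                           homologs = length(unique(events$homolog_id[!ok]))))
  class(res) <- "duplication_map"
  res
}

#' @export
print.duplication_map <- function(x, ...) {
  cat(sprintf("gene duplications: %d total across %d homologs; %d mapped, %d unmapped\n",
              nrow(x$events), length(unique(x$events$homolog_id)),
              sum(!is.na(x$events$mapped_node)), x$unmapped[["events"]]))
  nz <- x$by_node[x$by_node$n_duplications > 0, , drop = FALSE]
  if (nrow(nz)) print.data.frame(nz, row.names = FALSE)
  invisible(x)
}

#' Detect and map gene duplications for a set of homolog trees
#'
#' Convenience wrapper running [find_duplications()] on every homolog tree
#' and [map_duplications()] against the species tree.
#'
#' @inheritParams map_conflicts
#' @return a `duplication_map`, see [map_duplications()].
#' @export
map_gene_duplications <- function(species_tree, gene_trees, min_support = 50,
                                  delimiter = "@",
                                  missing_support_fails = FALSE) {
  if (inherits(gene_trees, "phylo")) gene_trees <- list(gene_trees)
  ids <- names(gene_trees)
  if (is.null(ids)) ids <- sprintf("h%04d", seq_along(gene_trees))
  evs <- mapply(function(t, id)
    find_duplications(t, delimiter, min_support, missing_support_fails, id),
    gene_trees, ids, SIMPLIFY = FALSE)
  events <- do.call(rbind, evs)
  class(events) <- c("duplication_events", "data.frame")
  htax <- stats::setNames(lapply(gene_trees, function(t)
    sort(unique(taxon_name(t$tip.label, delimiter)))), ids)
  map_duplications(species_tree, events, htax, delimiter)
}

#' Write duplication outputs to disk
#'
#' Emits `"<prefix>.dups.node.tsv"` (per species node: event and homolog
#' counts) and `"<prefix>.dups.events.tsv"` (per event: taxon sets and
#' mapped node, `NA` when unmapped).
#'
#' @param x a `duplication_map` from [map_duplications()].
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
write_duplication_outputs <- function(x, prefix) {
  stopifnot(inherits(x, "duplication_map"))
  f1 <- paste0(prefix, ".dups.node.tsv")
  utils::write.table(x$by_node, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  ev <- data.frame(
    homolog_id = x$events$homolog_id,
    union_taxa = vapply(x$events$union_taxa, paste, character(1), collapse = ";"),
    shared_taxa = vapply(x$events$shared_taxa, paste, character(1), collapse = ";"),
    support = x$events$support,
    mapped_node = x$events$mapped_node,
    mrca_node = x$events$mrca_node, stringsAsFactors = FALSE)
  f2 <- paste0(prefix, ".dups.events.tsv")
  utils::write.table(ev, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(f1, f2))
}
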