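# Per-homolog summary statistics and their contrast between concordant and
# conflicting homolog sets at each species-tree node.

#' Summary statistics for one homolog tree
#'
#' Computes the average root-to-tip path length (a proxy for the clade's
#' average molecular substitution rate when branch lengths are in
#' substitutions/site), the proportion of internal non-root edges with
#' bootstrap support strictly greater than `support_threshold` (edges
#' without support are excluded from numerator and denominator), and the
#' average bootstrap value over internal non-root edges that carry support.
#'
#' Note the two thresholds in play across the package differ at the
#' boundary: this proportion uses a strict "greater than", while the
#' bipartition filter of [decompose_bipartitions()] ignores only edges
#' strictly below its threshold (so exactly-threshold edges are kept there).
#'
#' @param tree a rooted homolog `phylo`.
#' @param support_threshold percent threshold for "supported" edges
#'   (default 50).
#' @param delimiter taxon delimiter for tip labels.
#' @param homolog_id identifier for the output row.
#' @return one-row data frame: `homolog_id`, `avg_root_to_tip`,
#'   `prop_supported_edges`, `avg_support`, `n_taxa`, `n_informative_edges`.
#' @export
homolog_stats <- function(tree, support_threshold = 50, delimiter = "@",
                          homolog_id = "") {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  avg_rtt <- if (is.null(tree$edge.length)) NA_real_ else
    mean(ape::node.depth.edgelength(tree)[seq_len(ntip)])
  sup <- node_support(tree)
  sup_nr <- if (tree$Nnode > 1L) sup[-1L] else numeric()  # drop root
  have <- !is.na(sup_nr)
  data.frame(
    homolog_id = homolog_id,
    avg_root_to_tip = avg_rtt,
    prop_supported_edges = if (any(have)) mean(sup_nr[have] > support_threshold)
                           else NA_real_,
    avg_support = if (any(have)) mean(sup_nr[have]) else NA_real_,
    n_taxa = length(unique(taxon_name(tree$tip.label, delimiter))),
    n_informative_edges = sum(sup_nr[have] > support_threshold),
    stringsAsFactors = FALSE)
}

#' Summary statistics for a set of homolog trees
#'
#' @inheritParams homolog_stats
#' @param trees list of rooted homolog `phylo` trees (names = homolog ids).
#' @return data frame, one row per homolog (see [homolog_stats()]).
#' @export
homolog_stats_table <- function(trees, support_threshold = 50,
                                delimiter = "@") {
  if (inherits(trees, "phylo")) trees <- list(trees)
  ids <- names(trees)
  if (is.null(ids)) ids <- sprintf("h%04d", seq_along(trees))
  do.call(rbind, mapply(function(t, id)
    homolog_stats(t, support_threshold, delimiter, id),
    trees, ids, SIMPLIFY = FALSE))
}

#' Contrast homolog statistics between concordant and conflicting sets
#'
#' For each species-tree node, averages each homolog statistic over the
#' homologs concordant with the node and over those in conflict with it, and
#' reports the difference (concordant minus conflicting). An empty side is
#' reported as `NA`, not zero.
#'
#' @param stats data frame from [homolog_stats_table()].
#' @param conflict a `node_conflict` object from [map_conflicts()] (its
#'   membership provides the per-node homolog id sets).
#' @return long-format data frame: `node_id`, `statistic`,
#'   `mean_concordant`, `mean_conflicting`, `difference`.
#' @export
contrast_stats <- function(stats, conflict) {
  stopifnot(inherits(conflict, "node_conflict"))
  vars <- c("avg_root_to_tip", "prop_supported_edges", "avg_support")
  rows <- list()
  for (nid in names(conflict$membership)) {
    mem <- conflict$membership[[nid]]
    sc <- stats[stats$homolog_id %in% mem$concordant, vars, drop = FALSE]
    sf <- stats[stats$homolog_id %in% mem$conflicting, vars, drop = FALSE]
    for (v in vars) {
      mc <- if (nrow(sc)) mean(sc[[v]], na.rm = TRUE) else NA_real_
      mf <- if (nrow(sf)) mean(sf[[v]], na.rm = TRUE) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        node_id = as.integer(nid), statistic = v,
        mean_concordant = mc, mean_conflicting = mf,
        difference = mc - mf, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write homolog statistics and node contrasts to disk
#'
#' Emits `"<prefix>.homstats.tsv"` and `"<prefix>.contrast.node.tsv"`.
#'
#' @inheritParams contrast_stats
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
write_homstats_outputs <- function(stats, conflict, prefix) {
  f1 <- paste0(prefix, ".homstats.tsv")
  utils::write.table(stats, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  ct <- contrast_stats(stats, conflict)
  f2 <- paste0(prefix, ".contrast.node.tsv")
  utils::write.table(ct, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(f1, f2))
}
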