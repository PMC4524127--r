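# Internal tree helpers shared across modules. Trees are ape "phylo" objects;
# bootstrap support rides in node.label (normalized to percent at read time).

.root_node <- function(tree) length(tree$tip.label) + 1L

# children of every node as a list indexed by ape node number
.children_list <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  ch <- vector("list", n)
  e <- tree$edge
  for (i in seq_len(nrow(e))) ch[[e[i, 1L]]] <- c(ch[[e[i, 1L]]], e[i, 2L])
  ch
}

.parent_vec <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  p <- rep(NA_integer_, n)
  p[tree$edge[, 2L]] <- tree$edge[, 1L]
  p
}

# topological depth (edges from root) of every node
.node_depths <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  d <- rep(NA_integer_, n)
  d[.root_node(tree)] <- 0L
  ord <- ape::reorder.phylo(tree, "cladewise")$edge
  for (i in seq_len(nrow(ord))) d[ord[i, 2L]] <- d[ord[i, 1L]] + 1L
  d
}

# taxon set (gene copies collapsed) of the clade below every node, postorder
.clade_taxa <- function(tree, delimiter = "@") {
  ntip <- length(tree$tip.label)
  n <- ntip + tree$Nnode
  taxa <- vector("list", n)
  tip_tax <- taxon_name(tree$tip.label, delimiter)
  for (i in seq_len(ntip)) taxa[[i]] <- tip_tax[i]
  post <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(post))) {
    p <- post[i, 1L]; c <- post[i, 2L]
    taxa[[p]] <- c(taxa[[p]], taxa[[c]])
  }
  lapply(taxa, function(x) sort(unique(x)))
}

# preorder 0-based ids for internal nodes (root = 0), named by ape node number
.preorder_ids <- function(tree) {
  ntip <- length(tree$tip.label)
  e <- ape::reorder.phylo(tree, "cladewise")$edge
  internal <- c(.root_node(tree), e[e[, 2L] > ntip, 2L])
  ids <- seq_along(internal) - 1L
  names(ids) <- internal
  ids
}

.bip_key <- function(ingroup, outgroup) {
  paste0(paste(ingroup, collapse = ","), "|", paste(outgroup, collapse = ","))
}

# normalize a numeric support value to percent; idempotent
.normalize_support_num <- function(v) {
  out <- v
  prop <- !is.na(v) & v >= 0 & v <= 1
  out[prop] <- v[prop] * 100
  out
}

#' Per-node bootstrap support of a tree
#'
#' Reads internal node labels of an ape `phylo` tree and returns the numeric
#' support values in percent. Labels that parse as numbers in `[0, 1]` are
#' interpreted as proportions and scaled by 100; values in `(1, 100]` are
#' taken as percentages; non-numeric or absent labels give `NA`. The
#' normalization is idempotent.
#'
#' @param tree an ape `phylo` object.
#' @return numeric vector of length `tree$Nnode` (indexed as ape internal
#'   nodes, i.e. element 1 is the root when the tree is in cladewise order),
#'   with `NA` where no support is recorded.
#' @export
node_support <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  v <- suppressWarnings(as.numeric(tree$node.label))
  v[!is.na(v) & (v < 0 | v > 100)] <- NA_real_
  .normalize_support_num(v)
}

# does a support value pass the filter under the missing-support policy?
.passes_filter <- function(support, min_support, missing_support_fails = FALSE) {
  ifelse(is.na(support),
         !missing_support_fails | min_support <= 0,
         support >= min_support)
}
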