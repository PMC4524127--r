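# Reading and writing rooted newick trees with bootstrap support in internal
# node labels, taxon-name resolution for gene-copy tip labels, and extraction
# of rooted ingroup clades given an outgroup taxon set.

# lightweight syntax check so malformed input fails with a character offset
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "(") depth <- depth + 1L
    else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("newick parse error at character offset %d: unmatched ')'", i),
             call. = FALSE)
    } else if (ch == ";" && depth != 0L) {
      stop(sprintf("newick parse error at character offset %d: ';' inside an unclosed clade", i),
           call. = FALSE)
    }
  }
  if (depth != 0L)
    stop(sprintf("newick parse error at character offset %d: %d unclosed '('",
                 length(chars), depth), call. = FALSE)
  if (!any(chars == ";"))
    stop(sprintf("newick parse error at character offset %d: missing terminal ';'",
                 length(chars)), call. = FALSE)
  invisible(TRUE)
}

.normalize_tree_support <- function(tree) {
  if (is.null(tree$node.label)) return(tree)
  v <- suppressWarnings(as.numeric(tree$node.label))
  bad <- !is.na(v) & (v < 0 | v > 100)
  if (any(bad))
    stop("support value out of range [0, 100]: ", paste(tree$node.label[bad], collapse = ", "),
         call. = FALSE)
  v <- .normalize_support_num(v)
  lab <- tree$node.label
  lab[!is.na(v)] <- format(v[!is.na(v)], trim = TRUE, digits = 15)
  tree$node.label <- lab
  tree
}

.validate_parsed_tree <- function(tree) {
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "),
         "; encode gene copies of one taxon as distinct labels (e.g. taxon@copy)",
         call. = FALSE)
  .normalize_tree_support(tree)
}

#' Read rooted newick trees with support values
#'
#' Parses one or more newick strings into ape `phylo` trees. Numeric internal
#' node labels are interpreted as bootstrap support: values in `[0, 1]` are
#' treated as proportions and rescaled to percent, values in `(1, 100]` are
#' kept as percentages, and non-numeric labels are retained as plain labels.
#' Polytomies are preserved. Malformed newick raises an error naming the
#' offending character offset; duplicate tip labels are an error (gene copies
#' of one taxon must carry distinct labels, see [taxon_name()]).
#'
#' @param text character vector of newick strings (one tree each), or `NULL`.
#' @param file path to a newick file, one or more trees (one per line or
#'   `;`-separated); used when `text` is `NULL`.
#' @return a single `phylo` if one tree was read, otherwise a list of `phylo`
#'   objects (class `multiPhylo`).
#' @examples
#' tr <- read_newick("((A,B)95,C);")
#' node_support(tr)
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("supply either 'text' or 'file'")
    raw <- paste(readLines(file, warn = FALSE), collapse = "\n")
    text <- paste0(trimws(strsplit(raw, ";", fixed = TRUE)[[1]]), ";")
    text <- text[text != ";"]
    if (!length(text)) stop("no trees found in ", file)
  }
  trees <- lapply(text, function(s) {
    .check_newick_syntax(s)
    tr <- tryCatch(ape::read.tree(text = s),
                   error = function(e) stop("newick parse error: ", conditionMessage(e),
                                            call. = FALSE))
    if (is.null(tr)) stop("newick parse error: unparseable tree string", call. = FALSE)
    .validate_parsed_tree(tr)
  })
  if (length(trees) == 1L) return(trees[[1L]])
  class(trees) <- "multiPhylo"
  trees
}

#' Write trees to newick with support as internal node labels
#'
#' @param tree a `phylo` or list of `phylo` objects.
#' @param file output path, or `NULL` to return the newick string(s).
#' @param digits significant digits for branch lengths.
#' @return the newick string(s), invisibly when written to file.
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  if (inherits(tree, "phylo")) tree <- list(tree)
  txt <- vapply(tree, function(t) ape::write.tree(t, digits = digits), character(1))
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Resolve taxon names from gene-copy tip labels
#'
#' Tip labels of homolog trees encode a taxon plus a gene-copy identifier,
#' separated by a delimiter (`"taxon@copy"` by convention). The taxon is the
#' text before the *first* delimiter; labels lacking the delimiter map to
#' themselves, so species-tree tips pass through unchanged.
#'
#' @param labels character vector of tip labels.
#' @param delimiter single-character delimiter (default `"@"`).
#' @return character vector of taxon names, same length as `labels`.
#' @examples
#' taxon_name(c("Apis@g00123", "Apis", "Atriplex@x@y"))
#' @export
taxon_name <- function(labels, delimiter = "@") {
  stopifnot(is.character(labels), nchar(delimiter) == 1L)
  vapply(strsplit(labels, delimiter, fixed = TRUE), `[[`, character(1), 1L)
}

#' Extract rooted ingroup clades from a homolog tree
#'
#' Given a (possibly arbitrarily rooted) homolog tree and a set of outgroup
#' taxa, reroots the tree on the outgroup tip topologically closest to the
#' current root (ties broken by lexicographic tip label) and returns every
#' maximal subtree whose tips are all ingroup taxa. Subtrees with fewer than
#' three distinct taxa are discarded since they carry no non-trivial rooted
#' bipartition. When no outgroup tip is present the tree is returned unchanged
#' as a single clade only if `assume_rooted = TRUE`; otherwise an error asks
#' for that flag.
#'
#' @param tree a `phylo` homolog tree.
#' @param outgroup_taxa non-empty character vector of outgroup taxon names.
#' @param delimiter taxon delimiter for tip labels, see [taxon_name()].
#' @param assume_rooted treat a tree with no outgroup tips as already rooted.
#' @return list of `phylo` rooted ingroup clades (possibly empty).
#' @export
extract_rooted_ingroups <- function(tree, outgroup_taxa, delimiter = "@",
                                    assume_rooted = FALSE) {
  stopifnot(inherits(tree, "phylo"), length(outgroup_taxa) >= 1L)
  tip_tax <- taxon_name(tree$tip.label, delimiter)
  og <- which(tip_tax %in% outgroup_taxa)
  if (!length(og)) {
    if (!assume_rooted)
      stop("no outgroup taxa found among the tips; if the tree is already rooted, ",
           "set assume_rooted = TRUE (--assume-rooted)", call. = FALSE)
    if (length(unique(tip_tax)) < 3L) return(list())
    return(list(tree))
  }
  depths <- .node_depths(tree)
  cand <- og[order(depths[og], tree$tip.label[og])]
  rt <- tryCatch(
    ape::root(tree, outgroup = tree$tip.label[cand[1L]], resolve.root = TRUE),
    error = function(e) tree)
  tip_tax <- taxon_name(rt$tip.label, delimiter)
  ntip <- length(rt$tip.label)
  n <- ntip + rt$Nnode
  # a node is ingroup-only iff every tip below it is an ingroup taxon
  ingroup_ok <- rep(TRUE, n)
  ingroup_ok[seq_len(ntip)] <- !(tip_tax %in% outgroup_taxa)
  post <- ape::reorder.phylo(rt, "postorder")$edge
  for (i in seq_len(nrow(post))) {
    p <- post[i, 1L]; ch <- post[i, 2L]
    if (!ingroup_ok[ch]) ingroup_ok[p] <- FALSE
  }
  parent <- .parent_vec(rt)
  clade_tax <- .clade_taxa(rt, delimiter)
  out <- list()
  for (node in (ntip + 1L):n) {
    if (!ingroup_ok[node]) next
    p <- parent[node]
    if (!is.na(p) && ingroup_ok[p]) next  # not maximal
    if (length(clade_tax[[node]]) < 3L) next
    out[[length(out) + 1L]] <- ape::extract.clade(rt, node)
  }
  out
}
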