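# Rooted-bipartition decomposition of homolog trees: one (ingroup | outgroup)
# taxon-set statement per internal non-root edge, with gene copies collapsed
# to taxon names, bootstrap filtering, and pooling across homologs.

#' Construct a rooted bipartition
#'
#' A rooted bipartition is an (ingroup | outgroup) pair of disjoint taxon
#' sets induced by an internal edge of a rooted tree: the ingroup lies toward
#' the tips, the outgroup toward the root. Rooting distinguishes grades from
#' clades, which unrooted splits cannot.
#'
#' @param ingroup character vector of taxon names toward the tips (>= 2).
#' @param outgroup character vector of taxon names toward the root (>= 1).
#' @param support bootstrap support in percent, or `NA`.
#' @param homolog_id identifier of the source homolog tree.
#' @param node ape node number of the source node (opaque handle).
#' @return an object of class `rooted_bipartition`.
#' @export
rooted_bipartition <- function(ingroup, outgroup, support = NA_real_,
                               homolog_id = "", node = NA_integer_) {
  ingroup <- sort(unique(as.character(ingroup)))
  outgroup <- sort(unique(as.character(outgroup)))
  if (length(ingroup) < 2L) stop("ingroup must contain at least 2 taxa")
  if (length(outgroup) < 1L) stop("outgroup must be non-empty")
  if (length(intersect(ingroup, outgroup)))
    stop("ingroup and outgroup must be disjoint")
  structure(list(ingroup = ingroup, outgroup = outgroup,
                 support = as.numeric(support), homolog_id = homolog_id,
                 node = node),
            class = "rooted_bipartition")
}

#' @export
print.rooted_bipartition <- function(x, ...) {
  cat(sprintf("(%s | %s)", paste(x$ingroup, collapse = ","),
              paste(x$outgroup, collapse = ",")))
  if (!is.na(x$support)) cat(sprintf("  support=%g", x$support))
  cat("\n")
  invisible(x)
}

# decompose to a data.frame (internal workhorse; keeps every bipartition and
# records whether it passes the filter, so callers can treat pass/fail edges
# differently, e.g. for the grey category)
.decompose_df <- function(tree, delimiter = "@", min_support = 0,
                          missing_support_fails = FALSE, homolog_id = "") {
  ntip <- length(tree$tip.label)
  n <- ntip + tree$Nnode
  clade <- .clade_taxa(tree, delimiter)
  full <- clade[[.root_node(tree)]]
  sup <- node_support(tree)
  internal <- setdiff((ntip + 1L):n, .root_node(tree))
  rows <- lapply(internal, function(node) {
    ing <- clade[[node]]
    if (length(ing) < 2L) return(NULL)
    outg <- setdiff(full, ing)
    if (!length(outg)) return(NULL)
    list(node = node, ingroup = ing, outgroup = outg,
         support = sup[node - ntip])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(homolog_id = character(), node = integer(),
                      support = numeric(), pass = logical(),
                      key = character(), in_str = character(),
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(
    homolog_id = homolog_id,
    node = vapply(rows, `[[`, integer(1), "node"),
    support = vapply(rows, `[[`, numeric(1), "support"),
    stringsAsFactors = FALSE)
  df$pass <- .passes_filter(df$support, min_support, missing_support_fails)
  df$ingroup <- lapply(rows, `[[`, "ingroup")
  df$outgroup <- lapply(rows, `[[`, "outgroup")
  df$in_str <- vapply(df$ingroup, paste, character(1), collapse = ",")
  df$key <- mapply(.bip_key, df$ingroup, df$outgroup)
  df
}

#' Decompose a rooted tree into rooted bipartitions
#'
#' Every internal non-root node of a rooted ingroup homolog clade induces one
#' rooted bipartition: the taxa of its clade (gene copies collapsed, so a
#' clade with tips `A@1, A@2, B` against remaining taxa `C,D,E` is recorded
#' as `(A,B | C,D,E)`) versus the remaining taxa of that tree. The root
#' bipartition (empty outgroup) and bipartitions whose collapsed ingroup
#' reduces to a single taxon are dropped as trivial. Bipartitions on edges
#' whose bootstrap support fails `min_support` are excluded; edges without
#' support pass by default (absence is not evidence of low support), unless
#' `missing_support_fails` is set.
#'
#' @param tree a rooted `phylo` tree with >= 3 distinct taxa.
#' @param delimiter taxon delimiter for tip labels, see [taxon_name()].
#' @param min_support bootstrap filter in percent; edges with support below
#'   this value are ignored (support equal to the threshold is kept).
#' @param missing_support_fails if `TRUE`, edges lacking support fail any
#'   positive filter instead of passing.
#' @param homolog_id identifier recorded on each bipartition.
#' @return list of [rooted_bipartition()] objects (possibly empty).
#' @export
decompose_bipartitions <- function(tree, delimiter = "@", min_support = 0,
                                   missing_support_fails = FALSE,
                                   homolog_id = "") {
  df <- .decompose_df(tree, delimiter, min_support, missing_support_fails,
                      homolog_id)
  df <- df[df$pass, , drop = FALSE]
  lapply(seq_len(nrow(df)), function(i)
    rooted_bipartition(df$ingroup[[i]], df$outgroup[[i]], df$support[i],
                       df$homolog_id[i], df$node[i]))
}

#' Pool unique bipartitions across homolog trees
#'
#' Decomposes each homolog tree and compiles the set of all unique rooted
#' bipartitions, recording both the total number of extracted (node-level)
#' bipartitions and the number of unique taxon-set statements, together with
#' each statement's multiplicity and the set of contributing homologs. The
#' published "numbers of bipartitions" language is ambiguous between totals
#' and uniques, so both are reported.
#'
#' @inheritParams decompose_bipartitions
#' @param trees list of rooted `phylo` homolog trees; names are used as
#'   homolog ids (defaults to `h0001...`).
#' @return object of class `bipartition_pool`: a data frame with columns
#'   `key`, `in_str`, `out_str`, `multiplicity`, `n_homologs`, plus
#'   attributes `n_total` (all extracted bipartitions) and `n_unique`.
#' @export
bipartition_pool <- function(trees, delimiter = "@", min_support = 0,
                             missing_support_fails = FALSE) {
  stopifnot(length(trees) >= 1L)
  if (inherits(trees, "phylo")) trees <- list(trees)
  ids <- names(trees)
  if (is.null(ids)) ids <- sprintf("h%04d", seq_along(trees))
  dfs <- mapply(function(t, id)
    .decompose_df(t, delimiter, min_support, missing_support_fails, id),
    trees, ids, SIMPLIFY = FALSE)
  df <- do.call(rbind, dfs)
  df <- df[df$pass, , drop = FALSE]
  if (!nrow(df)) {
    pool <- data.frame(key = character(), in_str = character(),
                       out_str = character(), multiplicity = integer(),
                       n_homologs = integer(), stringsAsFactors = FALSE)
  } else {
    out_str <- vapply(df$outgroup, paste, character(1), collapse = ",")
    agg <- split(seq_len(nrow(df)), df$key)
    pool <- data.frame(
      key = names(agg),
      in_str = df$in_str[vapply(agg, `[`, integer(1), 1L)],
      out_str = out_str[vapply(agg, `[`, integer(1), 1L)],
      multiplicity = vapply(agg, length, integer(1)),
      n_homologs = vapply(agg, function(i) length(unique(df$homolog_id[i])),
                          integer(1)),
      stringsAsFactors = FALSE, row.names = NULL)
    pool <- pool[order(-pool$multiplicity, pool$in_str), , drop = FALSE]
    rownames(pool) <- NULL
  }
  attr(pool, "n_total") <- nrow(df)
  attr(pool, "n_unique") <- nrow(pool)
  attr(pool, "min_support") <- min_support
  class(pool) <- c("bipartition_pool", "data.frame")
  pool
}

#' @export
print.bipartition_pool <- function(x, ...) {
  cat(sprintf("bipartition pool: %d total extracted, %d unique (filter >= %g%%)\n",
              attr(x, "n_total"), attr(x, "n_unique"), attr(x, "min_support")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... and %d more\n", nrow(x) - 10L))
  invisible(x)
}

#' Export a bipartition table to TSV
#'
#' Writes one row per (homolog, node) bipartition with semicolon-joined,
#' sorted taxon sets.
#'
#' @inheritParams bipartition_pool
#' @param file output path.
#' @return invisibly, the exported data frame.
#' @export
write_bipartitions_tsv <- function(trees, file, delimiter = "@",
                                   min_support = 0,
                                   missing_support_fails = FALSE) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  ids <- names(trees)
  if (is.null(ids)) ids <- sprintf("h%04d", seq_along(trees))
  dfs <- mapply(function(t, id)
    .decompose_df(t, delimiter, min_support, missing_support_fails, id),
    trees, ids, SIMPLIFY = FALSE)
  df <- do.call(rbind, dfs)
  df <- df[df$pass, , drop = FALSE]
  out <- data.frame(
    homolog_id = df$homolog_id,
    ingroup = vapply(df$ingroup, paste, character(1), collapse = ";"),
    outgroup = vapply(df$outgroup, paste, character(1), collapse = ";"),
    support = df$support, stringsAsFactors = FALSE)
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
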