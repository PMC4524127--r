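test_that("decomposition collapses gene copies and drops trivial bipartitions", {
  # clade with tips A@1, A@2, B against remaining taxa C, D, E
  tr <- read_newick("(((A@1,A@2,B),C),(D,E));")
  bips <- decompose_bipartitions(tr)
  keys <- vapply(bips, function(b)
    paste(paste(b$ingroup, collapse = ","), paste(b$outgroup, collapse = ","),
          sep = "|"), character(1))
  expect_true("A,B|C,D,E" %in% keys)
  # the (A@1, A@2) cherry collapses to one taxon: dropped as trivial
  expect_false(any(grepl("^A\\|", keys)))

  tr2 <- read_newick("((A,B),C);")
  bips2 <- decompose_bipartitions(tr2)
  expect_length(bips2, 1)
  expect_equal(bips2[[1]]$ingroup, c("A", "B"))
  expect_equal(bips2[[1]]$outgroup, "C")
})

test_that("a resolved rooted tree on n taxa yields n - 2 bipartitions", {
  set.seed(3)
  for (n in c(5, 8, 12)) {
    tr <- ape::rtree(n)
    expect_length(decompose_bipartitions(tr), n - 2)
  }
})

test_that("decomposition agrees with the prop.part oracle and is rotation invariant", {
  set.seed(11)
  for (i in 1:10) {
    tr <- ape::rtree(sample(5:10, 1))
    tr$node.label <- c("", sample(0:100, tr$Nnode - 1, TRUE))
    mine <- decompose_bipartitions(tr, min_support = 0)
    orac <- oracle_biparts(tr)
    key <- function(b) paste(paste(b$ingroup, collapse = ","),
                             paste(b$outgroup, collapse = ","), sep = "|")
    expect_setequal(vapply(mine, key, character(1)),
                    vapply(orac, key, character(1)))
    # child-order rotation changes nothing
    rot <- ape::rotateConstr(tr, rev(tr$tip.label))
    expect_setequal(vapply(decompose_bipartitions(rot, min_support = 0), key,
                           character(1)),
                    vapply(mine, key, character(1)))
    # every emitted bipartition satisfies the type invariants
    for (b in mine) {
      expect_gte(length(b$ingroup), 2)
      expect_gte(length(b$outgroup), 1)
      expect_length(intersect(b$ingroup, b$outgroup), 0)
    }
  }
})

test_that("pool multiplicity counts sources and unique keys deduplicate", {
  tr <- read_newick("(((A,B),C),(D,E));")
  pool <- bipartition_pool(list(h1 = tr, h2 = tr))
  expect_equal(attr(pool, "n_total"), 2 * length(decompose_bipartitions(tr)))
  expect_equal(attr(pool, "n_unique"), length(decompose_bipartitions(tr)))
  expect_true(all(pool$multiplicity == 2))
  expect_true(all(pool$n_homologs == 2))
})

test_that("bipartition counts are non-increasing in the bootstrap filter", {
  fx <- generate_fixture(fixture_spec(n_taxa = 10, n_homologs = 60,
                                      conflict_rate = 0.3, seed = 5))
  totals <- uniques <- numeric(4)
  for (k in seq_along(c(0, 20, 50, 80))) {
    pool <- bipartition_pool(fx$gene_trees,
                             min_support = c(0, 20, 50, 80)[k])
    totals[k] <- attr(pool, "n_total")
    uniques[k] <- attr(pool, "n_unique")
  }
  expect_true(all(diff(totals) <= 0))
  expect_true(all(diff(uniques) <= 0))
})

test_that("missing support passes filters by default and fails when asked", {
  tr <- read_newick("(((A,B),C),(D,E));")  # no support at all
  expect_length(decompose_bipartitions(tr, min_support = 80), 3)
  expect_length(decompose_bipartitions(tr, min_support = 80,
                                       missing_support_fails = TRUE), 0)
})
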