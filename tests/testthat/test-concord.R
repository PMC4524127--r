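bp <- function(ing, outg) list(ingroup = ing, outgroup = outg)

test_that("concordance and conflict follow the rooted ingroup/outgroup rules", {
  expect_true(is_concordant(bp(c("A", "B"), c("C", "D", "E")),
                            bp(c("A", "B"), c("C", "D", "E"))))
  # C sits in the ingroup of s, not its outgroup: not concordant
  expect_false(is_concordant(bp(c("A", "B"), "C"),
                             bp(c("A", "B", "C"), c("D", "E"))))
  # straddling ingroups: all three intersections non-empty
  expect_true(is_conflicting(bp(c("A", "B"), c("C", "D")),
                             bp(c("A", "C"), c("B", "D"))))
  # nested with empty ingroup(h)-outgroup(s) intersection: uninformative
  h <- bp(c("A", "B"), c("C", "D")); s <- bp(c("A", "B", "C"), "D")
  expect_false(is_concordant(h, s))
  expect_false(is_conflicting(h, s))
})

test_that("concordance/conflict match brute force and are mutually exclusive on all 5-taxon pairs", {
  all_bips <- enumerate_rooted_biparts(LETTERS[1:5])
  for (h in all_bips) {
    for (s in all_bips) {
      conc <- is_concordant(h, s)
      confl <- is_conflicting(h, s)
      expect_identical(conc, naive_concordant(h, s))
      expect_identical(confl, naive_conflicting(h, s))
      expect_false(conc && confl)
    }
  }
})

test_that("a homolog identical to the species tree is concordant everywhere with ICA 1", {
  sp <- read_newick("(((((A,B),C),D),E),F);")
  nc <- map_conflicts(sp, list(h1 = sp), min_support = 0)
  expect_true(all(nc$summary$n_concordant == 1))
  expect_true(all(nc$summary$n_conflicting == 0))
  expect_true(all(nc$summary$ica == 1))
})

test_that("edges below the filter vote grey, not concordant", {
  sp <- read_newick("((((A,B),C),D),E);")
  g <- sp
  g$node.label <- c("", rep("40", sp$Nnode - 1))
  nc <- map_conflicts(sp, list(h1 = g), min_support = 50)
  expect_true(all(nc$summary$n_concordant == 0))
  expect_true(all(nc$summary$n_grey == 1))
  expect_true(all(nc$summary$prop_grey == 1))
})

test_that("per-node counts equal the exhaustive pairwise mapper on a perturbed fixture", {
  fx <- generate_fixture(fixture_spec(n_taxa = 8, n_homologs = 50,
                                      conflict_rate = 0.4,
                                      conflict_nodes = c(1, 3), seed = 21))
  for (filt in c(0, 50)) {
    nc <- map_conflicts(fx$species_tree, fx$gene_trees, min_support = filt)
    orac <- oracle_map(fx$species_tree, fx$gene_trees, min_support = filt)
    joined <- merge(merge(nc$summary, nc$node_key, by = "node_id"),
                    orac, by = "in_str")
    expect_equal(joined$n_concordant.x, joined$n_concordant.y)
    expect_equal(joined$n_conflicting.x, joined$n_conflicting.y)
    expect_equal(joined$n_grey.x, joined$n_grey.y)
  }
})

test_that("alternative grouping merges containments and keeps incompatible statements apart", {
  b1 <- rooted_bipartition(c("A", "B"), c("C", "D", "E"), homolog_id = "h1")
  b2 <- rooted_bipartition(c("A", "B"), c("C", "D"), homolog_id = "h2")
  g <- group_alternatives(list(b1, b2))
  expect_equal(nrow(g), 1)
  expect_equal(g$n_homologs, 2)

  c1 <- rooted_bipartition(c("A", "C"), c("B", "D"), homolog_id = "h1")
  c2 <- rooted_bipartition(c("A", "D"), c("B", "C"), homolog_id = "h2")
  g2 <- group_alternatives(list(c1, c2))
  expect_equal(nrow(g2), 2)
  expect_equal(g2$n_homologs, c(1, 1))
})

test_that("a homolog can appear in several groups so group counts may exceed the conflict count", {
  # the reduced-sampling statement of h1 is contained in two incompatible
  # higher-frequency statements, so it joins both groups
  mk <- function(ing, outg, hid) rooted_bipartition(ing, outg, homolog_id = hid)
  bips <- list(mk(c("A", "B", "X"), c("C", "D"), "h2"),
               mk(c("A", "B", "X"), c("C", "D"), "h3"),
               mk(c("A", "B", "Y"), c("C", "D"), "h4"),
               mk(c("A", "B", "Y"), c("C", "D"), "h5"),
               mk(c("A", "B"), c("C", "D"), "h1"))
  g <- group_alternatives(bips)
  expect_equal(nrow(g), 2)
  expect_equal(g$n_homologs, c(3, 3))  # h1 counted in both groups
  expect_gt(sum(g$n_homologs), 5)
})

test_that("ICA matches closed forms and the evenness (majorization) behavior", {
  expect_identical(compute_ica(100), 1)
  expect_equal(compute_ica(50, 50), 0)
  p <- c(0.6, 0.3, 0.1)
  expect_equal(compute_ica(60, c(30, 10)),
               1 + sum(p * log(p, base = 3)), tolerance = 1e-12)
  # more even distributions at fixed b give lower certainty
  expect_lt(compute_ica(40, c(35, 25)), compute_ica(80, c(15, 5)))
  expect_error(compute_ica(0, c(0, 0)), "zero")
  # bounded in [0, 1] across random count vectors
  set.seed(8)
  for (i in 1:50) {
    v <- sample(0:50, sample(1:5, 1), replace = TRUE)
    if (all(v == 0)) next
    ica <- compute_ica(v[1], v[-1])
    expect_gte(ica, 0); expect_lte(ica, 1)
  }
})

test_that("conflict summaries round-trip to disk in the documented formats", {
  fx <- generate_fixture(fixture_spec(n_taxa = 6, n_homologs = 20,
                                      conflict_rate = 0.25, seed = 2))
  nc <- map_conflicts(fx$species_tree, fx$gene_trees, min_support = 0)
  dir <- withr::local_tempdir()
  paths <- write_conflict_outputs(nc, file.path(dir, "run"))
  expect_true(all(file.exists(paths)))
  tab <- read.delim(file.path(dir, "run.concord.node.tsv"))
  expect_equal(tab$n_concordant, nc$summary$n_concordant)
  # raw read: node-id labels must not be reinterpreted as support values
  key_tree <- ape::read.tree(file.path(dir, "run.species.nodekey.tre"))
  expect_equal(sort(as.integer(key_tree$node.label)),
               sort(c(0L, nc$summary$node_id)))
})

test_that("homolog taxa missing from the species tree are reported by name", {
  sp <- read_newick("((A,B),C);")
  g <- read_newick("((A,B),(C,ZZ));")
  expect_error(map_conflicts(sp, list(g)), "ZZ")
})
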