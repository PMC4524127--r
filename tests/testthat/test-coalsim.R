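test_that("pure-birth trees are ultrametric, deterministic under seed, and sized right", {
  tr <- sim_pure_birth(2, seed = 1)
  expect_equal(length(tr$tip.label), 2)
  expect_true(ape::is.ultrametric(tr))
  expect_error(sim_pure_birth(1), ">= 2")

  a <- sim_pure_birth(50, seed = 99)
  b <- sim_pure_birth(50, seed = 99)
  expect_identical(ape::write.tree(a), ape::write.tree(b))
  expect_equal(length(a$tip.label), 50)
  expect_true(ape::is.ultrametric(a))
})

test_that("pure-birth root heights match the Yule expectation", {
  set.seed(17)
  n_rep <- 600
  hts <- replicate(n_rep, max(ape::node.depth.edgelength(sim_pure_birth(10))))
  expected <- sum(1 / (2:10))   # unit birth rate
  se <- sd(hts) / sqrt(n_rep)
  expect_lt(abs(mean(hts) - expected), 4 * se)
})

test_that("root-height rescaling is linear, exact, and invertible", {
  tr <- sim_pure_birth(12, seed = 3)
  h0 <- max(ape::node.depth.edgelength(tr))
  doubled <- rescale_root_height(tr, 2 * h0)
  expect_equal(doubled$edge.length, 2 * tr$edge.length, tolerance = 1e-12)
  same <- rescale_root_height(tr, h0)
  expect_equal(same$edge.length, tr$edge.length, tolerance = 1e-12)
  back <- rescale_root_height(rescale_root_height(tr, 10), h0)
  expect_equal(back$edge.length, tr$edge.length, tolerance = 1e-9)
  expect_equal(max(ape::node.depth.edgelength(rescale_root_height(tr, 10))),
               10, tolerance = 1e-9)
  caterpillar <- read_newick("((A:1,B:2):1,C:4);")
  expect_error(rescale_root_height(caterpillar, 10), "ultrametric")
})

test_that("MSC gene trees carry the species tips, are ultrametric, and respect branch bounds", {
  st <- rescale_root_height(sim_pure_birth(8, seed = 5), 5)
  genes <- sim_msc(st, 25, seed = 6)
  for (g in genes) {
    expect_setequal(g$tip.label, st$tip.label)
    expect_true(ape::is.ultrametric(g, tol = 1e-8))
  }
  # determinism
  g2 <- sim_msc(st, 25, seed = 6)
  expect_identical(vapply(genes, ape::write.tree, character(1)),
                   vapply(g2, ape::write.tree, character(1)))
})

test_that("3-taxon concordance matches the closed form 1 - (2/3)exp(-t)", {
  has_ab <- function(g) ape::getMRCA(g, c("A", "B")) != length(g$tip.label) + 1L
  n <- 3000
  for (t in c(0.5, 2)) {
    st <- read_newick(sprintf("((A:1,B:1):%g,C:%g);", t, 1 + t))
    genes <- sim_msc(st, n, seed = 100 + t)
    frac <- mean(vapply(genes, has_ab, logical(1)))
    p0 <- 1 - (2 / 3) * exp(-t)
    expect_lt(abs(frac - p0), 3 * sqrt(p0 * (1 - p0) / n))
  }
  # hard polytomy limit: the three topologies are equally likely
  st0 <- read_newick("((A:1,B:1):0,C:1);")
  genes0 <- sim_msc(st0, n, seed = 9)
  frac0 <- mean(vapply(genes0, has_ab, logical(1)))
  expect_lt(abs(frac0 - 1 / 3), 3 * sqrt((1 / 3) * (2 / 3) / n))
})

test_that("random pruning removes the rounded tip count and induces the restricted subtree", {
  tr <- sim_pure_birth(50, seed = 12)
  expect_identical(prune_random(tr, 0), tr)
  p <- prune_random(tr, 0.1, seed = 2)
  expect_equal(length(p$tip.label), 45)
  expect_induced_subtree(p, tr)
  small <- sim_pure_birth(4, seed = 1)
  expect_error(prune_random(small, 0.6), "fewer than 3")
})

test_that("coalescent null curves are rank-monotone and collapse at large heights", {
  # a well-separated tree: every internal branch is a third of the height,
  # so at height 30 each spans 10 coalescent units and deep coalescence is
  # vanishingly rare
  st <- read_newick(paste0("(((A:1,B:1):1,(C:1,D:1):1):1,",
                           "((E:1,F:1):1,(G:1,H:1):1):1);"))
  null <- conflict_null(st, root_heights = c(30), n_genes = 150, seed = 4)
  # deep coalescence is rare at height 30: conflict proportions near zero
  alt <- null$curves[null$curves$rank > 0, ]
  expect_true(nrow(alt) == 0 || max(alt$prop) < 0.05)
  null2 <- conflict_null(st, root_heights = c(2, 30), n_genes = 150, seed = 4)
  for (nid in unique(null2$curves$node_id)) {
    for (h in c(2, 30)) {
      sub <- null2$curves[null2$curves$node_id == nid &
                          null2$curves$height == h & null2$curves$rank > 0, ]
      if (nrow(sub) > 1) expect_true(all(diff(sub$prop[order(sub$rank)]) <= 0))
    }
  }
  expect_true(all(null2$envelope$prop_min <= null2$envelope$prop_max))
})
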