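test_that("the canonical two-copy clade is one duplication; distinct taxa give none", {
  tr <- read_newick("(((A@1,B@1),(A@2,B@2)),C@1);")
  ev <- find_duplications(tr, min_support = 0)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$shared_taxa[[1]], c("A", "B"))
  expect_setequal(ev$union_taxa[[1]], c("A", "B"))

  tr2 <- read_newick("(((A@1,B@1),C@1),D@1);")
  expect_equal(nrow(find_duplications(tr2, min_support = 0)), 0)

  # a single shared taxon is never an event (power loss toward the tips)
  tr3 <- read_newick("(((A@1,B@1),(A@2,C@1)),D@1);")
  ev3 <- find_duplications(tr3, min_support = 0)
  expect_true(all(vapply(ev3$shared_taxa, length, integer(1)) >= 2))
  expect_equal(nrow(ev3), 0)
})

test_that("nested duplications are each detected via the carried union", {
  tr <- read_newick("((((A@1,B@1),(A@2,B@2)),(A@3,B@3)),C@1);")
  ev <- find_duplications(tr, min_support = 0)
  expect_equal(nrow(ev), 2)
  # exhaustive check: every internal node's children intersections
  ntip <- length(tr$tip.label)
  expected <- 0L
  for (v in (ntip + 1):(ntip + tr$Nnode)) {
    kids <- tr$edge[tr$edge[, 1] == v, 2]
    sets <- lapply(kids, function(k) {
      tips <- if (k <= ntip) k else
        ape::prop.part(tr)[[k - ntip]]
      unique(taxon_name(tr$tip.label[tips]))
    })
    tax <- unlist(sets)
    if (length(unique(tax[duplicated(tax)])) >= 2) expected <- expected + 1L
  }
  expect_equal(nrow(ev), expected)
})

test_that("the local bootstrap filter requires focal and internal children to pass", {
  txt <- "(((A@1,B@1)%s,(A@2,B@2)%s)%s,C@1);"
  ok <- read_newick(sprintf(txt, "90", "90", "90"))
  expect_equal(nrow(find_duplications(ok, min_support = 50)), 1)
  low_child <- read_newick(sprintf(txt, "30", "90", "90"))
  expect_equal(nrow(find_duplications(low_child, min_support = 50)), 0)
  low_focal <- read_newick(sprintf(txt, "90", "90", "30"))
  expect_equal(nrow(find_duplications(low_focal, min_support = 50)), 0)
  # tip children are exempt from the filter: two bare-tip copies plus one
  # supported internal child still qualify at a polytomy
  tipdup <- read_newick("((A@1,B@1,(A@2,B@2)90)80,C@1);")
  expect_equal(nrow(find_duplications(tipdup, min_support = 50)), 1)
  # raising the filter never adds events
  set.seed(4)
  fx <- generate_fixture(fixture_spec(n_taxa = 8, n_homologs = 30,
                                      dup_plan = data.frame(node_id = c(1, 2),
                                                            n_events = c(3, 2)),
                                      seed = 13))
  counts <- vapply(c(0, 20, 50, 80), function(f)
    nrow(map_gene_duplications(fx$species_tree, fx$gene_trees,
                               min_support = f)$events), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detection is invariant to child order and copy-label permutation", {
  tr <- read_newick("(((A@1,B@1),(A@2,B@2)),C@1);")
  rot <- ape::rotateConstr(tr, rev(tr$tip.label))
  expect_equal(nrow(find_duplications(rot, min_support = 0)), 1)
  swapped <- tr
  swapped$tip.label <- sub("@1", "@9", swapped$tip.label)
  ev <- find_duplications(swapped, min_support = 0)
  expect_equal(ev$shared_taxa[[1]], c("A", "B"))
})

test_that("events map to the shallowest concordant node; conflicting unions stay unmapped", {
  sp <- read_newick("(((A,B),C),D);")
  # union {A,B} -> the (A,B) node
  g1 <- read_newick("((((A@1,B@1),(A@2,B@2)),C@1),D@1);")
  dm1 <- map_gene_duplications(sp, list(h1 = g1), min_support = 0)
  nid_ab <- dm1$by_node$node_id[dm1$by_node$n_duplications == 1]
  key <- map_conflicts(sp, list(h1 = sp))$node_key
  expect_equal(key$in_str[key$node_id == nid_ab], "A,B")
  # union {A, C} conflicts with the species clades: unmapped
  g2 <- read_newick("((((A@1,C@1),(A@2,C@2)),B@1),D@1);")
  dm2 <- map_gene_duplications(sp, list(h1 = g2), min_support = 0)
  expect_equal(sum(dm2$by_node$n_duplications), 0)
  expect_equal(unname(dm2$unmapped["events"]), 1)
  # union spanning the whole homolog maps to the MRCA of the union
  g3 <- read_newick("(((A@1,B@1),C@1),((A@2,B@2),C@2));")
  sp3 <- read_newick("(((A,B),C),D);")
  dm3 <- map_gene_duplications(sp3, list(h1 = g3), min_support = 0)
  nid <- dm3$events$mapped_node
  expect_equal(key$in_str[key$node_id == nid], "A,B,C")
})

test_that("mapped events and homologs never exceed totals", {
  fx <- generate_fixture(fixture_spec(n_taxa = 10, n_homologs = 40,
                                      conflict_rate = 0.2,
                                      dup_plan = data.frame(node_id = c(2, 4),
                                                            n_events = c(4, 3)),
                                      seed = 31))
  dm <- map_gene_duplications(fx$species_tree, fx$gene_trees, min_support = 0)
  n_mapped <- sum(!is.na(dm$events$mapped_node))
  expect_lte(n_mapped, nrow(dm$events))
  expect_lte(length(unique(dm$events$homolog_id[!is.na(dm$events$mapped_node)])),
             length(unique(dm$events$homolog_id)))
})
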