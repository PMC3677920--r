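test_that("newick parsing validates and round-trips", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  expect_s3_class(tr, "phylo")
  d <- ape::node.depth.edgelength(tr)[1:3]
  expect_equal(unname(d), c(2, 2, 2))

  # round trip preserves content up to child ordering
  set.seed(7)
  rt <- ape::rtree(10)
  back <- read_newick(write_newick(rt))
  expect_equal(leaf_distances(back), leaf_distances(rt), tolerance = 1e-8)

  expect_error(read_newick("((A:1,B:1"), "parse")
  expect_error(read_newick("((A:1,A:1):1,C:2);"), "duplicate")

  # missing branch lengths become zero
  tr0 <- read_newick("((A,B),C);")
  expect_true(all(tr0$edge.length == 0))
})

test_that("pruning preserves path lengths among kept taxa", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  expect_equal(leaf_distances(prune_to_taxa(tr, c("A", "B", "C"))),
    leaf_distances(tr))
  two <- prune_to_taxa(tr, c("A", "C"))
  expect_equal(unname(leaf_distances(two)["A", "C"]), 4)
  expect_error(prune_to_taxa(tr, c("A", "Z")), "Z")

  set.seed(11)
  for (rep in 1:5) {
    tr8 <- ape::rtree(8)
    keep <- sample(tr8$tip.label, 5)
    full <- leaf_distances(tr8)[sort(keep), sort(keep)]
    expect_equal(leaf_distances(prune_to_taxa(tr8, keep)), full,
      tolerance = 1e-10)
  }
})

test_that("ultrametricity check follows the relative tolerance", {
  expect_true(is_ultrametric_tree(read_newick("((A:1,B:1):1,C:2);")))
  expect_false(is_ultrametric_tree(read_newick("((A:1,B:2):1,C:2);")))
  # perturbation below tolerance passes, above fails
  expect_true(is_ultrametric_tree(
    read_newick("((A:1,B:1.0000001):1,C:2.0000001);"), 1e-6))
  expect_false(is_ultrametric_tree(
    read_newick("((A:1,B:1.01):1,C:2.01);"), 1e-6))
})

test_that("backbone constraint satisfaction matches the clade definition", {
  tr <- read_newick("(((A:1,B:1):1,C:2):1,D:3);")
  expect_true(satisfies_backbone(tr, tr)) # fully resolved copy
  star <- read_newick("(A,B,C,D);")
  expect_true(satisfies_backbone(tr, star))

  # rooted triplets: only the matching resolution passes
  t1 <- read_newick("((A:1,B:1):1,C:2);")
  expect_true(satisfies_backbone(t1, read_newick("((A,B),C);")))
  expect_false(satisfies_backbone(t1, read_newick("((A,C),B);")))
  expect_false(satisfies_backbone(t1, read_newick("((B,C),A);")))

  # constraint on a taxon subset is checked on the pruned tree
  expect_true(satisfies_backbone(tr, read_newick("((A,B),D);")))
  expect_false(satisfies_backbone(tr, read_newick("((A,D),C);")))
})

test_that("backbone filtering preserves order and is idempotent", {
  set.seed(3)
  trees <- lapply(1:10, function(i) {
    tr <- ape::rtree(5)
    tr$tip.label <- sample(c("A", "B", "C", "D", "E"))
    tr
  })
  sample10 <- tree_sample(trees)
  constraint <- read_newick("((A,B),(C,D,E));")
  keep <- vapply(sample10, satisfies_backbone, logical(1), constraint)
  filtered <- filter_by_backbone(sample10, constraint)
  expect_length(filtered, sum(keep))
  if (sum(keep) > 0) {
    expect_identical(
      vapply(filtered, write_newick, character(1)),
      vapply(unclass(sample10)[keep], write_newick, character(1))
    )
    twice <- filter_by_backbone(filtered, constraint)
    expect_length(twice, length(filtered))
  }
  star <- read_newick("(A,B,C,D,E);")
  expect_length(filter_by_backbone(sample10, star), 10)
  impossible <- read_newick("(((A,C),B),(D,E));")
  incompat <- Filter(function(t) !satisfies_backbone(t, impossible),
    unclass(sample10))
  if (length(incompat) > 0) {
    expect_warning(filter_by_backbone(tree_sample(incompat), impossible),
      "no tree")
  }
})

test_that("MCC tree maximizes the clade-frequency product", {
  t_a <- read_newick("(((A:1,B:1):1,C:2):1,D:3);")
  t_b <- read_newick("(((A:1,C:1):1,B:2):1,D:3);")
  all_same <- tree_sample(list(t_a, t_a, t_a))
  m <- max_clade_credibility(all_same)
  expect_equal(m$index, 1)
  expect_true(all(m$clade_freq == 1))

  mixed <- tree_sample(list(t_b, t_a, t_a))
  m2 <- max_clade_credibility(mixed)
  expect_equal(m2$index, 2) # first tree with the majority topology

  # clade frequencies equal brute-force counts / n
  counts <- table(unlist(lapply(mixed, coevotraits:::clade_keys)))
  freq <- m2$clade_freq
  names(freq) <- gsub(";", "\r", names(freq), fixed = TRUE)
  expect_equal(freq[names(counts)], as.numeric(counts) / 3,
    ignore_attr = TRUE)
})

test_that("tree samples validate shared taxa and survive file round trips", {
  t_a <- read_newick("((A:1,B:1):1,C:2);")
  t_bad <- read_newick("((A:1,X:1):1,C:2);")
  expect_error(tree_sample(list(t_a, t_bad)), "taxon set")
  path <- withr::local_tempfile(fileext = ".nwk")
  s <- tree_sample(list(t_a, t_a))
  write_tree_sample(s, path)
  back <- read_tree_sample(path)
  expect_length(back, 2)
  expect_equal(leaf_distances(back[[1]]), leaf_distances(t_a))
})
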