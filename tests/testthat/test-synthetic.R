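test_that("Yule trees have the right size, shape and determinism", {
  tr <- simulate_yule_tree(10, 1, seed = 1)
  expect_equal(length(tr$tip.label), 10)
  expect_true(is_ultrametric_tree(tr))
  tr2 <- simulate_yule_tree(10, 1, seed = 1)
  expect_identical(write_newick(tr), write_newick(tr2))
  expect_error(simulate_yule_tree(1, 1), "n_taxa")
})

test_that("Yule root heights match the pure-birth expectation", {
  # E[height] = sum_{k=2}^{n-1} 1 / (lambda k) under the stop-at-nth-birth
  # convention with tips extended to the last event
  lambda <- 1.3
  n <- 10
  set.seed(61)
  heights <- replicate(2000, {
    max(ape::node.depth.edgelength(simulate_yule_tree(n, lambda)))
  })
  expected <- sum(1 / (lambda * (2:(n - 1))))
  se <- stats::sd(heights) / sqrt(length(heights))
  expect_lt(abs(mean(heights) - expected), 3 * se)
})

test_that("tree samples share taxa and respect the jitter contract", {
  cfg <- scenario_config(n_taxa = 12, n_outgroup = 3, n_trees = 12,
    seed = 5)
  s <- simulate_tree_sample(cfg)
  expect_length(s, 12)
  labs <- sort(s[[1]]$tip.label)
  for (tr in s) {
    expect_identical(sort(tr$tip.label), labs)
    expect_true(is_ultrametric_tree(tr))
    # outgroup clade is monophyletic
    expect_true(satisfies_backbone(tr, read_newick(
      "((out1,out2,out3),(sp01,sp02,sp03,sp04,sp05,sp06,sp07,sp08,sp09));"
    )))
  }
  # identical per-tree seeds: jitter off reproduces the same trees
  cfg_j <- cfg
  cfg_j$jitter_sd <- 0.1
  s_j <- simulate_tree_sample(cfg_j)
  expect_identical(write_newick(s[[3]]),
    write_newick(simulate_tree_sample(cfg)[[3]]))
  expect_false(identical(write_newick(s_j[[3]]), write_newick(s[[3]])))
  # topologies are not all identical for n_taxa >= 6
  topo <- vapply(s, function(t) {
    paste(sort(coevotraits:::clade_keys(t)), collapse = "|")
  }, character(1))
  expect_gt(length(unique(topo)), 1)
})

test_that("scenario datasets respect the male-character constraint", {
  for (scn in c("INDEPENDENT", "DEPENDENT", "PRECEDENCE", "MALE_CHAIN")) {
    for (seed in 1:3) {
      ds <- simulate_dataset(scenario_config(
        n_taxa = 12, n_outgroup = 2, n_trees = 2,
        scenario = scn, seed = seed
      ))
      male <- state_labels(ds$male)
      s <- state_labels(ds$s)
      # no taxon combines penile sacs with enhanced pedipalps
      expect_false(any(male == "S+P+"))
      expect_true(all(male %in% male_states()))
      # the male character is consistent with the S character
      expect_identical(unname(s == "S+"), unname(male == "S+P-"))
      # data round-trip through the standard readers
      path <- withr::local_tempfile(fileext = ".tsv")
      write_character_tsv(ds$sb, path)
      expect_equal(
        read_character_tsv(path, state_space = sb_states())$states,
        ds$sb$states
      )
    }
  }
})

test_that("near-zero rates give constant characters", {
  ds <- simulate_dataset(scenario_config(
    n_taxa = 8, n_outgroup = 0, n_trees = 1, scenario = "DEPENDENT",
    rates = rep(1e-9, 8), seed = 3
  ))
  expect_equal(length(unique(state_labels(ds$sb))), 1)
})

test_that("dependent scenarios produce stronger dwell association", {
  # project the true joint histories and compare mean M across scenarios
  map_s <- c("S+B-" = "S+", "S+B+" = "S+", "S-B+" = "S-", "S-B-" = "S-")
  map_b <- c("S+B-" = "B-", "S+B+" = "B+", "S-B+" = "B+", "S-B-" = "B-")
  m_for <- function(scn, seed) {
    ds <- simulate_dataset(scenario_config(
      n_taxa = 20, n_outgroup = 0, n_trees = 1, scenario = scn,
      seed = seed
    ))
    h <- ds$histories$sb
    hs <- history_project(h, map_s, c("S+", "S-"))
    hb <- history_project(h, map_b, c("B-", "B+"))
    association_stats(list(hs), list(hb), n_predictive = 0)$M
  }
  set.seed(91)
  m_dep <- vapply(1:25, function(s) m_for("DEPENDENT", s), numeric(1))
  m_ind <- vapply(1:25, function(s) m_for("INDEPENDENT", s + 100),
    numeric(1))
  expect_gt(mean(m_dep), mean(m_ind))
})

test_that("the 29-taxon fixture reproduces the published census", {
  fx <- make_paper_like_fixture()
  expect_equal(length(fx$tree$tip.label), 29)
  expect_true(is_ultrametric_tree(fx$tree))
  census <- table(state_labels(fx$sb))
  expect_equal(unname(census[["S+B+"]]), 2)
  expect_equal(unname(census[["S-B-"]]), 1)
  expect_equal(sum(census), 29)
  # deterministic
  fx2 <- make_paper_like_fixture()
  expect_identical(state_labels(fx2$sb), state_labels(fx$sb))
  expect_identical(write_newick(fx2$tree), write_newick(fx$tree))
  # the shipped extdata files agree with the in-code fixture
  tree_file <- system.file("extdata", "fig4like_synthetic_tree.nwk",
    package = "coevotraits")
  s_file <- system.file("extdata", "fig4like_synthetic_s.tsv",
    package = "coevotraits")
  expect_identical(read_newick(readLines(tree_file))$tip.label,
    fx$tree$tip.label)
  expect_equal(read_character_tsv(s_file, c("S+", "S-"))$states,
    fx$s$states)
})
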