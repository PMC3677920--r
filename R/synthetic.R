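## Synthetic data: Yule trees, posterior-like tree samples, and character
## data simulated under the package's trait-evolution scenarios, so every
## pipeline stage is testable without external downloads.

#' Scenario configuration for synthetic datasets
#'
#' Defaults emulate the harvestman study design: 29 taxa (25 ingroup plus
#' a 4-taxon outgroup clade), ultrametric Yule trees, and binary
#' penis/barrier characters evolved under one of four generating regimes.
#'
#' @param n_taxa Total taxon count (>= 4; default 29).
#' @param n_outgroup Taxa in the outgroup clade (default 4).
#' @param birth_rate Yule birth rate (default 1; tree heights are then of
#'   order `log(n_taxa)`).
#' @param n_trees Trees in the sample (default 100).
#' @param scenario One of `"INDEPENDENT"`, `"DEPENDENT"`, `"PRECEDENCE"`,
#'   `"MALE_CHAIN"`.
#' @param rates Optional named numeric of scenario rates; defaults are
#'   documented in the methods vignette (base rate 0.3 per unit height,
#'   with a 5x pull toward the concordant states under `"DEPENDENT"`).
#' @param jitter_sd Lognormal sd of multiplicative branch-length jitter
#'   emulating posterior spread (default 0 = off).
#' @param seed Master seed.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_taxa = 29L, n_outgroup = 4L, birth_rate = 1,
                            n_trees = 100L,
                            scenario = c(
                              "DEPENDENT", "INDEPENDENT",
                              "PRECEDENCE", "MALE_CHAIN"
                            ),
                            rates = NULL, jitter_sd = 0, seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(n_taxa >= 4L, n_outgroup >= 0L, n_outgroup < n_taxa - 1L,
            birth_rate > 0, n_trees >= 1L, jitter_sd >= 0)
  if (is.null(rates)) rates <- default_scenario_rates(scenario)
  stopifnot(all(rates > 0))
  structure(
    list(
      n_taxa = as.integer(n_taxa), n_outgroup = as.integer(n_outgroup),
      birth_rate = birth_rate, n_trees = as.integer(n_trees),
      scenario = scenario, rates = rates, jitter_sd = jitter_sd,
      seed = as.integer(seed)
    ),
    class = "scenario_config"
  )
}

default_scenario_rates <- function(scenario) {
  base <- 0.3
  switch(scenario,
    INDEPENDENT = c(
      s_loss = 2 * base, s_gain = base, b_gain = 2 * base, b_loss = base
    ),
    ## dep_8rate slot order; transitions *into* the concordant states
    ## (S+B-, S-B+) run 5x faster than into the discordant ones
    DEPENDENT = c(base, base, 5 * base, 5 * base, base, base,
                  5 * base, 5 * base),
    ## sac loss from the ancestral state much faster than barrier gain
    PRECEDENCE = c(0.05, 2, base, base, base, base, base, base),
    MALE_CHAIN = c(sac_loss = 2 * base, pedipalp_gain = 2 * base)
  )
}

## Deterministic per-stage, per-index seed derivation from a master seed.
derive_seed <- function(master, stage, index = 0L) {
  as.integer((as.numeric(master) * 131L + stage * 7919 + index * 104729) %%
    2147483647)
}

#' Simulate an ultrametric Yule tree
#'
#' Pure-birth process conditioned on the leaf count: the root split opens
#' two lineages at time zero; with `k` lineages the next split waits an
#' `Exp(birth_rate * k)` time; the process stops at the split creating the
#' `n_taxa`-th lineage and every tip extends to that last event time
#' (hence the expected root height is `sum_{k=2}^{n-1} 1/(birth_rate*k)`).
#'
#' @param n_taxa Number of leaves (>= 2).
#' @param birth_rate Birth rate (> 0).
#' @param seed Optional integer seed.
#' @param labels Optional tip labels (length `n_taxa`).
#' @return An ultrametric binary `phylo`.
#' @export
simulate_yule_tree <- function(n_taxa, birth_rate = 1, seed = NULL,
                               labels = NULL) {
  stopifnot(n_taxa >= 2L, birth_rate > 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(labels)) labels <- sprintf("t%02d", seq_len(n_taxa))
  stopifnot(length(labels) == n_taxa)
  ## nodes are temp ids; id 1 is the root, born (split) at time 0
  birth <- c(0, 0, 0) # birth time per temp id (root + first two lineages)
  parent <- c(NA_integer_, 1L, 1L)
  split_time <- c(0, NA_real_, NA_real_)
  alive <- c(2L, 3L)
  t_now <- 0
  nid <- 3L
  while (length(alive) < n_taxa) {
    k <- length(alive)
    t_now <- t_now + stats::rexp(1L, birth_rate * k)
    who <- alive[sample.int(k, 1L)]
    split_time[who] <- t_now
    c1 <- nid + 1L
    c2 <- nid + 2L
    nid <- nid + 2L
    birth[c(c1, c2)] <- t_now
    parent[c(c1, c2)] <- who
    split_time[c(c1, c2)] <- NA_real_
    alive <- c(setdiff(alive, who), c1, c2)
  }
  t_end <- t_now
  tip_label <- rep(NA_character_, nid)
  tip_label[alive] <- labels[seq_along(alive)]
  build <- function(id) {
    if (!is.na(tip_label[id])) {
      len <- t_end - birth[id]
      return(paste0(tip_label[id], ":", format(len, digits = 12)))
    }
    kids <- which(!is.na(parent) & parent == id)
    len <- if (id == 1L) 0 else split_time[id] - birth[id]
    paste0(
      "(", paste(vapply(kids, build, character(1L)), collapse = ","), "):",
      format(len, digits = 12)
    )
  }
  read_newick(paste0(sub(":0$", "", build(1L)), ";"))
}

## Compose an ingroup and an outgroup Yule tree into one rooted ultrametric
## tree with the outgroup monophyletic; stems pad both sides to a common
## height (half a mean waiting time above the deeper subtree).
yule_with_outgroup <- function(n_in, n_out, birth_rate, labels_in,
                               labels_out) {
  tin <- simulate_yule_tree(n_in, birth_rate, labels = labels_in)
  h_in <- max(ape::node.depth.edgelength(tin))
  if (n_out == 0L) {
    return(tin)
  }
  if (n_out == 1L) {
    nout <- labels_out
    h_out <- 0
  } else {
    tout <- simulate_yule_tree(n_out, birth_rate, labels = labels_out)
    h_out <- max(ape::node.depth.edgelength(tout))
    nout <- sub(";$", "", ape::write.tree(tout))
  }
  height <- max(h_in, h_out) + 0.5 / birth_rate
  nin <- sub(";$", "", ape::write.tree(tin))
  txt <- paste0(
    "(", nin, ":", format(height - h_in, digits = 12), ",",
    nout, ":", format(height - h_out, digits = 12), ");"
  )
  read_newick(txt)
}

#' Simulate a posterior-like sample of Yule trees
#'
#' Independent Yule trees over one shared taxon label set (an outgroup
#' clade is attached when `n_outgroup > 0`), optionally with lognormal
#' multiplicative branch-length jitter emulating posterior spread.  Tree
#' `i` is generated from a seed derived deterministically from the master
#' seed and `i`, so individual trees are reproducible in isolation.
#'
#' @param config A [scenario_config()] (or arguments via `...` to build
#'   one).
#' @return A `multiPhylo` tree sample.
#' @export
simulate_tree_sample <- function(config = scenario_config()) {
  n_in <- config$n_taxa - config$n_outgroup
  labels_in <- sprintf("sp%02d", seq_len(n_in))
  labels_out <- if (config$n_outgroup > 0L) {
    sprintf("out%d", seq_len(config$n_outgroup))
  } else {
    character(0L)
  }
  trees <- vector("list", config$n_trees)
  for (i in seq_len(config$n_trees)) {
    set.seed(derive_seed(config$seed, 1L, i))
    tr <- yule_with_outgroup(
      n_in, config$n_outgroup, config$birth_rate, labels_in, labels_out
    )
    if (config$jitter_sd > 0) {
      tr$edge.length <- tr$edge.length *
        stats::rlnorm(length(tr$edge.length), 0, config$jitter_sd)
    }
    trees[[i]] <- tr
  }
  tree_sample(trees, source = paste0("yule:", config$scenario))
}

## Binary component model specs used to build scenario generators.
spec_s_binary <- function() {
  tpl <- matrix(c(NA, 1L, 2L, NA), 2L, 2L, byrow = TRUE)
  rate_model_spec(tpl, c("S+", "S-"), name = "s_binary")
}
spec_b_binary <- function() {
  tpl <- matrix(c(NA, 1L, 2L, NA), 2L, 2L, byrow = TRUE)
  rate_model_spec(tpl, c("B-", "B+"), name = "b_binary")
}

#' Simulate a full synthetic dataset under a scenario
#'
#' Simulates a tree sample, then evolves the penis (S), barrier (B) and
#' 3-state male characters on the first tree of the sample under the
#' scenario's generator: `INDEPENDENT` uses the [joint_embedding()] of two
#' binary models, `DEPENDENT` and `PRECEDENCE` use [dep_8rate()]
#' generators (coupled, respectively sac-loss-first), and `MALE_CHAIN`
#' evolves the male character directly under [male_2rate()].  The male
#' character is derived from the S history plus an independent pedipalp
#' overlay masked so that `P+` never co-occurs with `S+`.  Simulation is
#' retried (deterministically within the seeded stream, at most 40 times)
#' until both binary characters vary at the tips, mirroring the
#' ascertainment of variable traits in real studies.
#'
#' @param config A [scenario_config()].
#' @return A list with `trees`, `s`, `b`, `male`, `sb` (joint 4-state),
#'   `histories` (true simulated histories), and `config`.
#' @export
simulate_dataset <- function(config = scenario_config()) {
  trees <- simulate_tree_sample(config)
  tr <- trees[[1L]]
  set.seed(derive_seed(config$seed, 2L))
  out <- NULL
  for (attempt in seq_len(40L)) {
    cand <- simulate_dataset_once(tr, config)
    s_var <- length(unique(stats::na.omit(cand$s$states))) == 2L
    b_var <- length(unique(stats::na.omit(cand$b$states))) == 2L
    if ((s_var && b_var) || attempt == 40L) {
      out <- cand
      break
    }
  }
  c(list(trees = trees), out, list(config = config))
}

simulate_dataset_once <- function(tr, config) {
  rates <- config$rates
  if (config$scenario == "MALE_CHAIN") {
    spec <- male_2rate(root_policy("fixed", "S+P-", male_states()))
    Q <- build_generator(spec, unname(rates))
    sim <- simulate_character(tr, Q, root = spec$root_policy)
    male <- sim$data
    s_lab <- ifelse(state_labels(male) == "S+P-", "S+", "S-")
    s <- character_data(s_lab, c("S+", "S-"))
    bQ <- build_generator(spec_b_binary(), c(0.3, 0.15))
    bsim <- simulate_character(tr, bQ, root = root_policy("fixed", 1L))
    return(list(
      s = s, b = bsim$data, male = male,
      sb = joint_character(s, bsim$data),
      histories = list(male = sim$history, b = bsim$history)
    ))
  }
  spec <- if (config$scenario == "INDEPENDENT") {
    joint_embedding(spec_s_binary(), spec_b_binary())
  } else {
    dep_8rate()
  }
  Q <- build_generator(spec, unname(rates))
  ## root fixed at the ancestral courtship state S+B-
  sim <- simulate_character(tr, Q, root = root_policy("fixed", 1L))
  sb <- sim$data
  parts <- split_joint_character(sb)
  s <- parts[[1L]]
  b <- parts[[2L]]
  ## pedipalp overlay: independent binary gain/loss, masked to S- taxa
  pQ <- build_generator(
    rate_model_spec(matrix(c(NA, 1L, 2L, NA), 2L, byrow = TRUE),
      c("P-", "P+"),
      name = "p_overlay"
    ),
    c(0.4, 0.1)
  )
  psim <- simulate_character(tr, pQ, root = root_policy("fixed", 1L))
  p_lab <- state_labels(psim$data)
  s_lab <- state_labels(s)
  male_lab <- ifelse(s_lab == "S+", "S+P-",
    ifelse(p_lab == "P+", "S-P+", "S-P-")
  )
  male <- character_data(male_lab, male_states())
  list(
    s = s, b = b, male = male, sb = sb,
    histories = list(sb = sim$history, p_overlay = psim$history)
  )
}

#' Hand-built 29-taxon fixture resembling the harvestman character census
#'
#' A synthetic, hard-coded ultrametric tree (25 ingroup + 4 outgroup taxa)
#' and tip states whose census matches the published counts: exactly two
#' taxa carry both sacs and barrier (S+B+), exactly one lacks both (S-B-),
#' and all remaining taxa are S+B- or S-B+, with the S-B+ taxa spread over
#' four separate clades.  The branching order is biologically plausible
#' but synthetic; it makes no claim of matching the true phylogeny.
#'
#' @param seed Unused (the fixture is fully deterministic); kept for a
#'   uniform generator signature.
#' @return A list with `tree`, `s`, `b`, `male`, `sb`.
#' @export
make_paper_like_fixture <- function(seed = 1L) {
  tree <- read_newick(fixture_newick())
  taxa <- tree$tip.label
  ns_taxa <- grep("^ns[ABC]", taxa, value = TRUE)
  hadro <- c("hgrandis_like", "hnsp3_like", "hmac_like", "hnsp2_like")
  s_minus <- c(ns_taxa, "hmac_like", "hnsp2_like", "relictum_like")
  b_plus <- c(ns_taxa, hadro)
  s_lab <- ifelse(taxa %in% s_minus, "S-", "S+")
  b_lab <- ifelse(taxa %in% b_plus, "B+", "B-")
  names(s_lab) <- names(b_lab) <- taxa
  s <- character_data(s_lab, c("S+", "S-"))
  b <- character_data(b_lab, c("B-", "B+"))
  enhanced <- grep("^ns[AB]", taxa, value = TRUE) # clasping pedipalps
  male_lab <- ifelse(s_lab == "S+", "S+P-",
    ifelse(taxa %in% enhanced, "S-P+", "S-P-")
  )
  names(male_lab) <- taxa
  list(
    tree = tree, s = s, b = b,
    male = character_data(male_lab, male_states()),
    sb = joint_character(s, b)
  )
}

## Ultrametric synthetic topology (height 3.0): an outgroup quartet plus
## an ingroup in which each barrier-bearing (non-sacculate) clade is
## sister to a sacculate, barrier-free clade, so the four gains (and the
## four-plus sac losses) are phylogenetically independent; one taxon
## lacks both structures.
fixture_newick <- function() {
  paste0(
    "(((out1:0.4,out2:0.4):0.5,(out3:0.4,out4:0.4):0.5):2.1,",
    "(((nsA1:1.0,(nsA2:0.75,(nsA3:0.5,(nsA4:0.25,nsA5:0.25):0.25):0.25)",
    ":0.25):1.0,",
    "((sacE1:0.3,sacE2:0.3):0.4,(sacE3:0.3,sacE4:0.3):0.4):1.3):0.5,",
    "((((nsB1:0.3,nsB2:0.3):0.4,(nsB3:0.3,nsB4:0.3):0.4):1.0,",
    "(sacF1:0.3,sacF2:0.3):1.4):0.5,",
    "(((nsC1:0.6,(nsC2:0.3,nsC3:0.3):0.3):0.8,(sacG1:0.3,sacG2:0.3):1.1)",
    ":0.5,",
    "(((hgrandis_like:0.3,hnsp3_like:0.3):0.5,",
    "(hmac_like:0.3,hnsp2_like:0.3):0.5):0.4,relictum_like:1.2):0.7)",
    ":0.3):0.3):0.5);"
  )
}
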