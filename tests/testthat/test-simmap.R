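test_that("prior discretizations integrate to one and fitters validate", {
  b <- coevotraits:::discretize_beta(5.9, 25)
  expect_equal(sum(b$weights), 1)
  expect_true(all(b$points > 0 & b$points < 1))
  g <- coevotraits:::discretize_gamma(3.5, 0.04, 25)
  expect_equal(sum(g$weights), 1)
  # quantile grid mean tracks the analytic mean
  expect_equal(sum(g$points * g$weights), 3.5 / 0.04, tolerance = 0.05)

  tr <- simulate_yule_tree(6, 1, seed = 2)
  d3 <- random_data(tr, 3)
  expect_error(fit_bias_prior(d3, tree_sample(list(tr))), "binary")
  d1 <- character_data(c(t01 = "0"), c("0", "1"))
  expect_error(fit_bias_prior(d1, tree_sample(list(tr))), ">= 2")
})

test_that("bias-prior fitting separates balanced from biased characters", {
  # balanced tips on a symmetric tree push alpha to the upper grid edge
  tr <- read_newick(
    "(((A:1,B:1):1,(C:1,D:1):1):1,((E:1,F:1):1,(G:1,H:1):1):1);")
  bal <- character_data(
    stats::setNames(rep(c("0", "1"), each = 4), tr$tip.label), c("0", "1"))
  a_bal <- fit_bias_prior(bal, tree_sample(list(tr)), n_grid = 11)
  expect_true(attr(a_bal, "boundary"))

  # characters evolved with a strong stationary bias admit extreme-bias
  # (alpha < 1) fits more often than characters evolved without bias
  n_rep <- 10
  a_skew <- numeric(n_rep)
  a_even <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    ty <- simulate_yule_tree(14, 1, seed = 500 + r)
    Qb <- binary_generator(0.9, 1.2, c("0", "1"))
    db <- simulate_character(ty, Qb,
      root = stationary_freqs(Qb), seed = 600 + r)$data
    Qe <- binary_generator(0.5, 1.2, c("0", "1"))
    de <- simulate_character(ty, Qe,
      root = stationary_freqs(Qe), seed = 700 + r)$data
    a_skew[r] <- fit_bias_prior(db, tree_sample(list(ty)), n_grid = 11)
    a_even[r] <- fit_bias_prior(de, tree_sample(list(ty)), n_grid = 11)
  }
  expect_gt(sum(a_skew < 1), sum(a_even < 1))
  # deterministic given identical inputs
  ty <- simulate_yule_tree(12, 1, seed = 401)
  lab <- stats::setNames(rep(c("0", "1"), 6), ty$tip.label)
  dd <- character_data(lab, c("0", "1"))
  expect_identical(
    fit_bias_prior(dd, tree_sample(list(ty)), n_grid = 11),
    fit_bias_prior(dd, tree_sample(list(ty)), n_grid = 11)
  )
})

test_that("rate-prior fitting recovers the generating rate scale", {
  set.seed(66)
  ratios <- numeric(8)
  for (r in seq_len(8)) {
    ty <- simulate_yule_tree(14, 1, seed = 700 + r)
    true_r <- 0.8
    Q <- binary_generator(0.5, true_r, c("0", "1"))
    d <- simulate_character(ty, Q, seed = 800 + r)$data
    if (length(unique(stats::na.omit(d$states))) < 2) next
    fit <- fit_rate_prior(d, tree_sample(list(ty)), n_grid = 9)
    ratios[r] <- (fit["shape"] / fit["rate"]) / true_r
  }
  ratios <- ratios[ratios > 0]
  expect_gt(length(ratios), 3)
  expect_true(median(ratios) > 1 / 3 && median(ratios) < 3)

  # a constant character fits a slower prior than a varying one
  ty <- simulate_yule_tree(12, 1, seed = 900)
  const <- character_data(
    stats::setNames(rep("0", 12), ty$tip.label), c("0", "1"))
  vary <- character_data(
    stats::setNames(rep(c("0", "1"), 6), ty$tip.label), c("0", "1"))
  f_const <- fit_rate_prior(const, tree_sample(list(ty)), n_grid = 9)
  f_vary <- fit_rate_prior(vary, tree_sample(list(ty)), n_grid = 9)
  expect_lt(f_const["shape"] / f_const["rate"],
    f_vary["shape"] / f_vary["rate"])
})

test_that("root posteriors match symmetry and enumeration oracles", {
  # constant character: near-point mass on the observed state
  ty <- simulate_yule_tree(10, 1, seed = 15)
  const <- character_data(
    stats::setNames(rep("1", 10), ty$tip.label), c("0", "1"))
  post <- root_marginal_posterior(tree_sample(list(ty)), const,
    prior_config(rate_prior = c(2, 10), n_grid = 9))
  expect_gt(post[["1"]], 0.99)

  # symmetric arrangement on a symmetric tree: exactly (1/2, 1/2)
  trs <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  d_sym <- character_data(c(A = "0", B = "0", C = "1", D = "1"),
    c("0", "1"))
  post_sym <- root_marginal_posterior(tree_sample(list(trs)), d_sym,
    prior_config(bias_prior = 4, rate_prior = c(2, 2), n_grid = 9))
  expect_equal(unname(post_sym), c(0.5, 0.5), tolerance = 1e-9)

  # near-point priors reduce to the fixed-Q enumeration posterior
  tr3 <- read_newick("((A:0.6,B:1.1):0.5,C:1.4);")
  d3 <- character_data(c(A = "0", B = "1", C = "0"), c("0", "1"))
  b_hat <- coevotraits:::empirical_bias(d3)
  r_fix <- 0.7
  post_pkg <- root_marginal_posterior(tree_sample(list(tr3)), d3,
    prior_config(rate_prior = c(1e6, 1e6 / r_fix), n_grid = 3))
  Qfix <- binary_generator(b_hat, r_fix, c("0", "1"))
  post_bf <- brute_force_root_posterior(tr3, d3, Qfix, c(1 - b_hat, b_hat))
  expect_equal(unname(post_pkg), post_bf, tolerance = 1e-3)
})

test_that("stochastic maps are consistent with the data and the posterior", {
  # near-zero generator with constant data: constant history
  ty <- read_newick("((A:1,B:1):1,C:2);")
  d_const <- character_data(c(A = "0", B = "0", C = "0"), c("0", "1"))
  Qeps <- binary_generator(0.5, 1e-9, c("0", "1"))
  h <- stochastic_map(ty, d_const, Qeps, seed = 2)
  expect_equal(history_changes(h), 0)
  expect_true(all(state_labels(history_tip_states(h)) == "0"))

  # maps always satisfy history invariants and end at observed tips
  set.seed(9)
  tr <- simulate_yule_tree(6, 1, seed = 44)
  Q <- binary_generator(0.4, 0.8, c("0", "1"))
  d <- simulate_character(tr, Q, seed = 45)$data
  for (s in 1:10) {
    hh <- stochastic_map(tr, d, Q, root = stationary_freqs(Q), seed = s)
    expect_equal(vapply(hh$maps, sum, numeric(1)), tr$edge.length,
      tolerance = 1e-9)
    obs <- d$states[tr$tip.label]
    expect_equal(hh$node_states[seq_along(obs)], unname(obs))
  }
})

test_that("free-endpoint change counts follow the Poisson mean rate*length", {
  tr <- read_newick("(A:5,B:0);")
  d_free <- character_data(c(A = "?", B = "?"), c("0", "1"))
  a <- 0.6
  Q <- matrix(c(-a, a, a, -a), 2, dimnames = list(c("0", "1"), c("0", "1")))
  set.seed(13)
  counts <- replicate(3000, {
    history_changes(stochastic_map(tr, d_free, Q))
  })
  # total jump rate a on a length-5 branch (plus the zero branch)
  expect_equal(mean(counts), a * 5, tolerance = 0.05)
})

test_that("conditioned paths match the uniformization oracle distribution", {
  Q <- matrix(c(-0.9, 0.9, 0.4, -0.4), 2, byrow = TRUE,
    dimnames = list(c("0", "1"), c("0", "1")))
  t_len <- 1.3
  P_t <- expm_series(Q * t_len)
  set.seed(17)
  n_draw <- 3000
  n_rej <- replicate(n_draw, {
    length(coevotraits:::sample_path_conditional(1L, 2L, t_len, Q, P_t,
      rejection_cap = 1e6)) - 1L
  })
  n_uni <- replicate(n_draw, {
    length(coevotraits:::sample_path_uniformization(1L, 2L, t_len, Q,
      P_t)) - 1L
  })
  tab_r <- tabulate(pmin(n_rej, 5) + 1L, nbins = 6)
  tab_u <- tabulate(pmin(n_uni, 5) + 1L, nbins = 6)
  keep <- (tab_r + tab_u) > 5
  gof <- suppressWarnings(stats::chisq.test(rbind(tab_r[keep], tab_u[keep])))
  expect_gt(gof$p.value, 0.01)
  # an odd-versus-even endpoint parity check: 0 -> 1 needs >= 1 change
  expect_true(all(n_rej >= 1) && all(n_uni >= 1))
})

test_that("map node-state marginals converge to enumeration marginals", {
  tr <- read_newick(
    "(((A:0.4,B:0.9):0.5,C:1.2):0.3,(D:0.8,E:0.3):0.6);")
  Q <- binary_generator(0.45, 0.9, c("0", "1"))
  d <- character_data(c(A = "0", B = "1", C = "0", D = "1", E = "0"),
    c("0", "1"))
  pi0 <- stationary_freqs(Q)
  maps <- stochastic_map(tr, d, Q, root = pi0, nsim = 10000, seed = 3)
  root_id <- 6L
  freq_root <- mean(vapply(maps, function(h) {
    h$node_states[root_id] == 1L
  }, logical(1)))
  post_root <- brute_force_root_posterior(tr, d, Q, pi0)
  expect_lt(abs(freq_root - post_root[1]), 0.02)
})

test_that("association statistics obey the self-pairing algebra", {
  set.seed(27)
  tr <- simulate_yule_tree(8, 1, seed = 71)
  Q <- binary_generator(0.5, 0.6, c("0", "1"))
  h <- simulate_character(tr, Q, seed = 72)$history
  stats_self <- association_stats(list(h), list(h), n_predictive = 0)
  p1 <- dwell_fractions(h)[["0"]]
  expect_equal(stats_self$m[1, 1], p1 * (1 - p1), tolerance = 1e-10)
  expect_equal(stats_self$m[1, 2], -p1 * (1 - p1), tolerance = 1e-10)
  # the m matrix rows and columns cancel exactly for a single pair
  expect_equal(sum(abs(rowSums(stats_self$m))), 0, tolerance = 1e-10)
  expect_error(association_stats(list(h), list(h, h)), "paired")
})

test_that("independent characters give associations centred on zero", {
  set.seed(35)
  n_rep <- 30
  m_means <- numeric(n_rep)
  m_abs <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    trees <- lapply(1:4, function(i) {
      simulate_yule_tree(8, 1, seed = 3000 + 10 * r + i)
    })
    m1 <- list()
    m2 <- list()
    for (tr in trees) {
      for (j in 1:2) {
        Q1 <- binary_generator(0.5, 2 / 3, c("0", "1"))
        Q2 <- binary_generator(0.5, 2 / 3, c("0", "1"))
        m1[[length(m1) + 1L]] <-
          simulate_character(tr, Q1, root = stationary_freqs(Q1))$history
        m2[[length(m2) + 1L]] <-
          simulate_character(tr, Q2, root = stationary_freqs(Q2))$history
      }
    }
    st <- association_stats(m1, m2, n_predictive = 0)
    m_means[r] <- mean(st$m)
    m_abs[r] <- st$m[1, 1]
  }
  # the cross-product structure forces mean(m) = 0 identically; the
  # individual components are centred near zero across replicates
  expect_lt(abs(mean(m_means)), 1e-10)
  expect_lt(abs(mean(m_abs)), 0.03)
})
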