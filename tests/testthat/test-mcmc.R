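# Shared small instance: one character on a few trees, cheap likelihoods.
mcmc_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- scenario_config(
        n_taxa = 10, n_outgroup = 2, n_trees = 5,
        scenario = "DEPENDENT", seed = 99
      )
      cache <<- simulate_dataset(cfg)
    }
    cache
  }
})

test_that("chains are bit-identical under a fixed seed", {
  ds <- mcmc_fixture()
  cfg <- mcmc_config(iterations = 400, thin = 4, seed = 5,
    rate_deviation = 0.6)
  t1 <- run_mcmc(ds$trees, ds$sb, dep_8rate(), cfg)
  t2 <- run_mcmc(ds$trees, ds$sb, dep_8rate(), cfg)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  # record-count contract
  expect_equal(nrow(t1), ceiling((400 - floor(400 * 0.3)) / 4))
  expect_true(all(is.finite(t1$lnL)))
})

test_that("state spaces must match between model and data", {
  ds <- mcmc_fixture()
  expect_error(
    run_mcmc(ds$trees, ds$s, dep_8rate(), mcmc_config(iterations = 10)),
    "state space"
  )
})

test_that("proposal tuning moves the deviation toward the target window", {
  ds <- mcmc_fixture()
  mock_pilot <- function(acc) {
    tr <- as.data.frame(matrix(0, 1000, 2))
    names(tr) <- c("iteration", "lnL")
    attr(tr, "acceptance_rate") <- acc
    class(tr) <- c("mcmc_trace", "data.frame")
    tr
  }
  cfg <- mcmc_config(rate_deviation = 0.5)
  expect_equal(tune_rate_deviation(mock_pilot(0.30), cfg), 0.5)
  expect_equal(tune_rate_deviation(mock_pilot(0.60), cfg), 1.0)
  expect_equal(tune_rate_deviation(mock_pilot(0.10), cfg), 0.25)
  cfg2 <- mcmc_config(rate_deviation = 1.5)
  expect_equal(tune_rate_deviation(mock_pilot(0.60), cfg2), 2.0) # capped
  expect_error(tune_rate_deviation(mock_pilot(0.3)[1:10, ], cfg), "1000")

  # iterated tuning on a real target enters the window within 10 rounds
  dev <- 2
  acc <- NA
  for (round in 1:10) {
    cfg_r <- mcmc_config(
      iterations = 1500, thin = 1, burn_in_fraction = 0.3,
      rate_deviation = dev, seed = 100 + round
    )
    pilot <- run_mcmc(ds$trees, ds$s, coevotraits:::spec_s_binary(), cfg_r)
    acc <- attr(pilot, "acceptance_rate")
    if (acc >= 0.2 && acc <= 0.4) break
    dev <- tune_rate_deviation(pilot, cfg_r)
  }
  expect_true((acc >= 0.2 && acc <= 0.4) || dev %in% c(0.001, 2))
})

test_that("effective sample size behaves on iid, correlated and constant input", {
  set.seed(77)
  x <- stats::rnorm(2000)
  ess_iid <- effective_sample_size(x)
  expect_gt(ess_iid, 0.85 * 2000)
  expect_lte(ess_iid, 2000)

  # strongly autocorrelated AR(1): far fewer effective draws
  ar <- as.numeric(stats::arima.sim(list(ar = 0.95), 2000))
  expect_lt(effective_sample_size(ar), 500)

  expect_warning(ess_c <- effective_sample_size(rep(1, 100)), "constant")
  expect_equal(ess_c, 100)
  expect_error(effective_sample_size(1:5), ">= 10")
})

test_that("posterior rate recovery improves with more data", {
  # RMSE of posterior-mean rates shrinks as taxa and trees grow
  true_rates <- c(0.4, 0.8, 1.2, 0.6, 0.9, 0.5, 1.0, 0.7)
  rmse_for <- function(n_taxa, n_trees, seed) {
    cfg <- scenario_config(
      n_taxa = n_taxa, n_outgroup = 0, n_trees = n_trees,
      scenario = "DEPENDENT", rates = true_rates, seed = seed
    )
    ds <- simulate_dataset(cfg)
    tr <- run_mcmc(ds$trees, ds$sb, dep_8rate(),
      mcmc_config(iterations = 2500, thin = 5, rate_deviation = 0.8,
        seed = seed))
    est <- colMeans(tr[, paste0("rate", 1:8)])
    sqrt(mean((est - true_rates)^2))
  }
  small <- mean(vapply(1:3, function(s) rmse_for(8, 2, s), numeric(1)))
  large <- mean(vapply(1:3, function(s) rmse_for(24, 10, s + 50), numeric(1)))
  expect_lt(large, small)
})

test_that("the sampler targets the grid-integrated posterior", {
  # one-parameter symmetric model on one tree: MCMC histogram vs direct
  # numerical posterior on a rate grid (uniform prior)
  set.seed(3)
  tr <- simulate_yule_tree(8, 1, seed = 12)
  spec1 <- rate_model_spec(matrix(c(NA, 1L, 1L, NA), 2, byrow = TRUE),
    c("0", "1"))
  Qtrue <- build_generator(spec1, 0.6)
  d <- simulate_character(tr, Qtrue, seed = 6)$data
  trees1 <- tree_sample(list(tr))
  trace <- run_mcmc(trees1, d, spec1,
    mcmc_config(iterations = 40000, thin = 1, rate_deviation = 0.8,
      prior = c(0, 10), seed = 8))
  # grid posterior over the same prior support
  grid <- seq(0.005, 10, by = 0.005)
  ll <- vapply(grid, function(r) {
    tree_log_likelihood(tr, d, build_generator(spec1, r))
  }, numeric(1))
  post <- exp(ll - max(ll))
  post <- post / sum(post)
  breaks <- seq(0, 10, by = 0.25)
  p_grid <- tapply(post, cut(grid, breaks), sum)
  p_grid[is.na(p_grid)] <- 0
  p_mcmc <- tabulate(cut(trace$rate1, breaks), nbins = length(breaks) - 1)
  p_mcmc <- p_mcmc / sum(p_mcmc)
  tv <- 0.5 * sum(abs(p_mcmc - p_grid))
  expect_lt(tv, 0.05)
})
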