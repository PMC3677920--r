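## Metropolis-Hastings sampling of transition rates over a posterior tree
## sample, with sliding-window proposals reflected at the prior bounds.

#' MCMC run configuration
#'
#' @param iterations Total chain length (default `5e5`; production-scale
#'   runs in the hundreds of millions are reachable by raising this).
#' @param burn_in_fraction Fraction of iterations discarded (default 0.30).
#' @param rate_deviation Sliding-window proposal half-width, in
#'   `[0.001, 2]` (default 0.5).
#' @param target_acceptance Acceptance-rate window aimed for when tuning
#'   (default `c(0.20, 0.40)`).
#' @param prior Uniform prior bounds on every rate, `c(lower, upper]`
#'   (default `c(0, 100)`).
#' @param thin Record every `thin`-th post-burn-in iteration (default 100).
#' @param seed Integer seed; every run is fully determined by it.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(iterations = 5e5, burn_in_fraction = 0.30,
                        rate_deviation = 0.5,
                        target_acceptance = c(0.20, 0.40),
                        prior = c(0, 100), thin = 100, seed = 1L) {
  stopifnot(
    iterations >= 1, burn_in_fraction > 0, burn_in_fraction < 1,
    rate_deviation > 0, thin >= 1,
    length(prior) == 2L, prior[2L] > prior[1L], prior[1L] >= 0
  )
  structure(
    list(
      iterations = as.integer(iterations),
      burn_in_fraction = burn_in_fraction,
      rate_deviation = rate_deviation,
      target_acceptance = target_acceptance,
      prior = prior, thin = as.integer(thin), seed = as.integer(seed)
    ),
    class = "mcmc_config"
  )
}

## Reflect a proposal into the open-below interval (lower, upper].
reflect <- function(x, lower, upper) {
  width <- upper - lower
  for (i in seq_len(100L)) {
    if (x > upper) {
      x <- 2 * upper - x
    } else if (x < lower) {
      x <- 2 * lower - x
    } else {
      break
    }
  }
  if (x <= lower) x <- lower + .Machine$double.eps * max(1, abs(lower))
  x
}

#' Sample rate parameters by Metropolis-Hastings over a tree sample
#'
#' Per iteration one rate, chosen uniformly, receives a sliding-window
#' perturbation of half-width `rate_deviation`, reflected at the prior
#' bounds, and the tree is independently resampled uniformly from the
#' sample; the joint proposal is accepted by likelihood ratio (the uniform
#' priors cancel).  Post-burn-in states are recorded every `thin`
#' iterations.
#'
#' @param trees A `multiPhylo` tree sample.
#' @param data A `character_data` over the model's state space.
#' @param spec A `rate_model_spec`.
#' @param config An [mcmc_config()].
#' @return A data frame of class `mcmc_trace` with columns `iteration`,
#'   `lnL`, `rate1..rateP`, `tree_index`, `accepted`, and attributes
#'   `config`, `acceptance_rate`, `model`.
#' @export
run_mcmc <- function(trees, data, spec, config = mcmc_config()) {
  stopifnot(inherits(spec, "rate_model_spec"))
  if (!setequal(spec$state_space, data$state_space)) {
    stop("model and data state spaces differ")
  }
  set.seed(config$seed)
  n_par <- spec$n_params
  lower <- config$prior[1L]
  upper <- config$prior[2L]
  preps <- lapply(trees, prepare_pruning, data = data)
  k <- spec$k
  tip_freq <- preps[[1L]]$tip_freq
  freqs <- resolve_root_freqs(spec$root_policy, k, tip_freq = tip_freq)
  max_t <- max(vapply(preps, function(p) max(p$lengths), numeric(1L)), 1e-8)

  loglik_at <- function(rates, tree_idx) {
    Q <- build_generator(spec, rates)
    Pfun <- transition_prob_fn(Q, check_t = max_t)
    loglik_prepared(preps[[tree_idx]], Pfun, freqs)
  }

  rates <- stats::runif(n_par, max(lower, 0.05), min(upper, 2))
  tree_idx <- sample.int(length(trees), 1L)
  ll <- loglik_at(rates, tree_idx)
  it_keep <- config$iterations - floor(config$iterations * config$burn_in_fraction)
  n_rec <- ceiling(it_keep / config$thin)
  rec <- matrix(NA_real_, n_rec, n_par + 4L)
  rec_i <- 0L
  burn_end <- config$iterations - it_keep
  n_acc <- 0L
  consec_rej <- 0L
  for (it in seq_len(config$iterations)) {
    j <- if (n_par > 1L) sample.int(n_par, 1L) else 1L
    prop <- rates
    prop[j] <- reflect(
      rates[j] + stats::runif(1L, -config$rate_deviation, config$rate_deviation),
      lower, upper
    )
    prop_tree <- sample.int(length(trees), 1L)
    prop_ll <- loglik_at(prop, prop_tree)
    accept <- is.finite(prop_ll) && log(stats::runif(1L)) < (prop_ll - ll)
    if (accept) {
      rates <- prop
      tree_idx <- prop_tree
      ll <- prop_ll
      n_acc <- n_acc + 1L
      consec_rej <- 0L
    } else {
      consec_rej <- consec_rej + 1L
      if (consec_rej > 1e5) {
        stop(
          "chain stuck: >1e5 consecutive rejections at lnL ", format(ll),
          "; lower rate_deviation or check the model"
        )
      }
    }
    if (it > burn_end && (it - burn_end) %% config$thin == 1L %% config$thin) {
      rec_i <- rec_i + 1L
      rec[rec_i, ] <- c(it, ll, rates, tree_idx, as.numeric(accept))
    }
  }
  trace <- as.data.frame(rec[seq_len(rec_i), , drop = FALSE])
  names(trace) <- c(
    "iteration", "lnL", paste0("rate", seq_len(n_par)),
    "tree_index", "accepted"
  )
  attr(trace, "config") <- config
  attr(trace, "acceptance_rate") <- n_acc / config$iterations
  attr(trace, "model") <- spec$name
  class(trace) <- c("mcmc_trace", "data.frame")
  trace
}

#' @export
print.mcmc_trace <- function(x, ...) {
  cat(
    "mcmc_trace:", nrow(x), "records, model", attr(x, "model"),
    ", acceptance", sprintf("%.3f", attr(x, "acceptance_rate")), "\n"
  )
  invisible(x)
}

#' Write / read a trace as tab-delimited text
#' @param trace An `mcmc_trace`.
#' @param path File path.
#' @export
write_trace_tsv <- function(trace, path) {
  utils::write.table(as.data.frame(trace), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_trace_tsv
#' @export
read_trace_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t")
  class(df) <- c("mcmc_trace", "data.frame")
  df
}

#' Adjust the proposal half-width toward the target acceptance window
#'
#' Multiplicative tuning by a factor of 2: the deviation doubles when the
#' pilot acceptance rate exceeds the window, halves when it falls below,
#' and is clamped to `[0.001, 2]`.
#'
#' @param pilot An `mcmc_trace` from a pilot run (>= 1000 records).
#' @param config The [mcmc_config()] used for the pilot.
#' @return The new rate deviation (scalar).
#' @export
tune_rate_deviation <- function(pilot, config) {
  if (nrow(pilot) < 1000L) stop("pilot needs >= 1000 records")
  acc <- attr(pilot, "acceptance_rate")
  dev <- config$rate_deviation
  lo <- config$target_acceptance[1L]
  hi <- config$target_acceptance[2L]
  if (acc > hi) dev <- dev * 2 else if (acc < lo) dev <- dev / 2
  min(max(dev, 0.001), 2)
}

#' Effective sample size of a trace parameter
#'
#' Autocorrelation-time ESS: `n / (1 + 2 * sum(rho_k))` with the
#' autocorrelation sum truncated by Geyer's initial positive-sequence rule
#' (stop at the first nonpositive pair sum).
#'
#' @param trace An `mcmc_trace` (or plain numeric vector via `parameter`
#'   left `NULL`).
#' @param parameter Column name, e.g. `"lnL"` or `"rate1"`.
#' @return The ESS (at most `n`).  A constant trace returns `n` with a
#'   degeneracy warning.
#' @export
effective_sample_size <- function(trace, parameter = "lnL") {
  x <- if (is.numeric(trace)) trace else trace[[parameter]]
  if (is.null(x)) stop("no such parameter: ", parameter)
  n <- length(x)
  if (n < 10L) stop("need >= 10 records")
  if (stats::var(x) == 0) {
    warning("constant trace: ESS reported as n")
    return(n)
  }
  lag_max <- min(n - 1L, max(50L, floor(10 * log10(n)) * 5L))
  rho <- as.numeric(stats::acf(x, lag.max = lag_max, plot = FALSE,
                               demean = TRUE)$acf)[-1L]
  tau <- 0
  i <- 1L
  while (i <= length(rho)) {
    pair <- rho[i] + if (i + 1L <= length(rho)) rho[i + 1L] else 0
    if (pair <= 0) break
    tau <- tau + pair
    i <- i + 2L
  }
  ess <- n / (1 + 2 * tau)
  min(ess, n)
}
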