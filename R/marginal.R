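## Marginal-likelihood approximation from MCMC log-likelihood traces
## (stabilized harmonic mean with bootstrap SE), Bayes factors and
## log-likelihood-ratio model comparison.

#' Stabilized harmonic-mean log marginal likelihood
#'
#' The Newton-Raftery estimator with the "small simulation" stabilization:
#' the marginal likelihood m solves the fixed point
#' \deqn{m = \frac{\delta n/(1-\delta) + \sum_i L_i / (\delta m + (1-\delta) L_i)}
#'                 {\delta n / ((1-\delta) m) + \sum_i 1 / (\delta m + (1-\delta) L_i)}}
#' over the sampled likelihoods `L_i`.  At `delta = 0` this reduces in one
#' step to the plain harmonic mean.  All arithmetic is done relative to the
#' largest log-likelihood to avoid underflow.
#'
#' @param loglik Numeric vector of sampled log-likelihoods.
#' @param delta Stabilization weight (default 0.01).
#' @param tol,max_iter Fixed-point convergence controls.
#' @return The log marginal-likelihood estimate (scalar).
#' @export
harmonic_mean_logml <- function(loglik, delta = 0.01, tol = 1e-12,
                                max_iter = 1000L) {
  stopifnot(length(loglik) >= 1L, all(is.finite(loglik)))
  c0 <- max(loglik)
  a <- exp(loglik - c0) # in (0, 1]
  n <- length(a)
  if (delta <= 0) {
    return(c0 - log(mean(1 / a)))
  }
  mu <- 1 / mean(1 / a) # start from the plain harmonic mean
  for (i in seq_len(max_iter)) {
    denom_i <- delta * mu + (1 - delta) * a
    num <- delta * n / (1 - delta) + sum(a / denom_i)
    den <- delta * n / ((1 - delta) * mu) + sum(1 / denom_i)
    mu_new <- num / den
    if (abs(mu_new - mu) <= tol * mu) {
      mu <- mu_new
      break
    }
    mu <- mu_new
  }
  c0 + log(mu)
}

#' Marginal-likelihood estimate container
#'
#' @param mean Log marginal likelihood.
#' @param se Standard error (>= 0).
#' @param n_bootstrap Number of bootstrap replicates behind `se`.
#' @return A list of class `logml_estimate`.
#' @export
logml_estimate <- function(mean, se = NA_real_, n_bootstrap = NA_integer_) {
  stopifnot(is.na(se) || se >= 0)
  structure(
    list(mean = mean, se = se, n_bootstrap = n_bootstrap),
    class = "logml_estimate"
  )
}

#' @export
print.logml_estimate <- function(x, ...) {
  cat(sprintf("log marginal likelihood %.3f +/- %.3f\n", x$mean, x$se))
  invisible(x)
}

logml_mean <- function(x) if (inherits(x, "logml_estimate")) x$mean else x

#' Marginal likelihood of a model from its MCMC trace
#'
#' Applies [harmonic_mean_logml()] to the post-burn-in log-likelihood
#' trace; the standard error comes from resampling the trace with
#' replacement.
#'
#' @param trace An `mcmc_trace` (or a numeric log-likelihood vector).
#' @param n_bootstrap Number of bootstrap replicates (default 1000).
#' @param seed Integer seed for the resampling.
#' @param delta Stabilization weight passed to [harmonic_mean_logml()].
#' @return A [logml_estimate()] whose `mean` is the estimate on the full
#'   trace and whose `se` is the bootstrap standard deviation.
#' @export
marginal_likelihood <- function(trace, n_bootstrap = 1000L, seed = 1L,
                                delta = 0.01) {
  if (n_bootstrap < 2L) stop("n_bootstrap must be >= 2")
  ll <- if (is.numeric(trace)) trace else trace$lnL
  est <- harmonic_mean_logml(ll, delta = delta)
  set.seed(seed)
  n <- length(ll)
  boots <- vapply(seq_len(n_bootstrap), function(b) {
    harmonic_mean_logml(ll[sample.int(n, n, replace = TRUE)], delta = delta)
  }, numeric(1L))
  logml_estimate(est, stats::sd(boots), n_bootstrap)
}

#' Bayes factor between two marginal-likelihood estimates
#'
#' Reported as the absolute difference of the log marginal likelihoods,
#' `K = |mean(a) - mean(b)|` (symmetric in its arguments).
#'
#' @param a,b [logml_estimate()] objects or bare log-scale numbers.
#' @return The Bayes factor K (log units).
#' @export
bayes_factor <- function(a, b) {
  abs(logml_mean(a) - logml_mean(b))
}

#' Log-likelihood-ratio test between nested models
#'
#' `chi2 = 2 * (mean(complex) - mean(simple))` referred to the chi-square
#' upper tail with `df` degrees of freedom.  Note the statistic is formed
#' from *marginal* (not maximum) likelihood approximations, mirroring the
#' BayesTraits-style workflow this package replicates; this is statistically
#' unorthodox and the p-values should be read as heuristic.  A negative
#' statistic is clamped to 0 with a warning.
#'
#' @param complex,simple [logml_estimate()]s or log-scale numbers, with
#'   `complex` the larger model.
#' @param df Degrees of freedom (>= 1); see [model_df()].
#' @return A list with `chi2`, `df` and `p`.
#' @export
likelihood_ratio_test <- function(complex, simple, df) {
  stopifnot(df >= 1)
  chi2 <- 2 * (logml_mean(complex) - logml_mean(simple))
  if (chi2 < 0) {
    warning("negative likelihood-ratio statistic clamped to 0")
    chi2 <- 0
  }
  p <- stats::pchisq(chi2, df = df, lower.tail = FALSE)
  structure(list(chi2 = chi2, df = df, p = p), class = "coevo_lrt")
}

#' @export
print.coevo_lrt <- function(x, ...) {
  cat(sprintf(
    "log-likelihood ratio test: chi2 = %.3f, d.f. = %d, p = %.4g\n",
    x$chi2, x$df, x$p
  ))
  invisible(x)
}

#' Pool independent runs of one model
#'
#' The pooled mean is the arithmetic mean of the run means; the pooled SE
#' is the arithmetic mean of the run SEs (the convention used when
#' tabulating per-run marginal likelihoods next to a "Mean" column).
#'
#' @param estimates A list of [logml_estimate()]s (>= 1).
#' @return A single [logml_estimate()].
#' @export
summarize_runs <- function(estimates) {
  stopifnot(length(estimates) >= 1L)
  means <- vapply(estimates, logml_mean, numeric(1L))
  ses <- vapply(
    estimates,
    function(e) if (inherits(e, "logml_estimate")) e$se else NA_real_,
    numeric(1L)
  )
  logml_estimate(mean(means), mean(ses),
    n_bootstrap = sum(vapply(estimates, function(e) {
      if (inherits(e, "logml_estimate") && !is.na(e$n_bootstrap)) {
        e$n_bootstrap
      } else {
        0L
      }
    }, integer(1L)))
  )
}

#' Compare two transition rates across independent runs
#'
#' For each run the posterior-mean difference between the two named rates
#' is computed; the per-run differences enter a two-tailed paired t-test
#' with `df = runs - 1`.
#'
#' @param traces A list (>= 2) of `mcmc_trace` objects fit under the same
#'   model.
#' @param rateA,rateB Parameter columns, as `"rateJ"` names or integer
#'   slot indices.
#' @return A list with `mean_diff`, `sd`, `t`, `df` and `p`.
#' @export
compare_transition_rates <- function(traces, rateA, rateB) {
  if (length(traces) < 2L) stop("need >= 2 runs")
  colname <- function(r) if (is.numeric(r)) paste0("rate", r) else r
  a <- colname(rateA)
  b <- colname(rateB)
  d <- vapply(traces, function(tr) {
    if (is.null(tr[[a]]) || is.null(tr[[b]])) {
      stop("trace lacks column ", a, " or ", b)
    }
    mean(tr[[a]]) - mean(tr[[b]])
  }, numeric(1L))
  n <- length(d)
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    if (m == 0) {
      return(list(mean_diff = 0, sd = 0, t = 0, df = n - 1L, p = 1))
    }
    warning("zero variance across runs; p reported as 0")
    return(list(
      mean_diff = m, sd = 0, t = sign(m) * Inf, df = n - 1L, p = 0
    ))
  }
  tstat <- m / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(tstat), df = n - 1L)
  list(mean_diff = m, sd = s, t = tstat, df = n - 1L, p = p)
}
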