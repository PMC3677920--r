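## Likelihood engine: Felsenstein pruning over a rooted tree with
## per-branch transition probabilities P(t) = exp(Q t).

#' Branch transition probabilities
#'
#' Builds a function `P(t)` returning the k x k transition-probability
#' matrix `exp(Q t)`.  An eigendecomposition of `Q` is used when it is
#' numerically diagonalizable (verified once against a scaling-and-squaring
#' exponential); otherwise every call falls back to [Matrix::expm()].
#' Tiny negative entries from roundoff are clamped to zero.
#'
#' @param Q A generator matrix (rows sum to zero).
#' @param check_t Branch length used for the one-off accuracy check.
#' @return A function of one nonnegative scalar `t`.
#' @export
transition_prob_fn <- function(Q, check_t = 1) {
  k <- nrow(Q)
  expm_fallback <- function(t) {
    P <- as.matrix(Matrix::expm(Q * t))
    P[P < 0] <- 0
    P
  }
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  use_eigen <- FALSE
  if (!is.null(eg)) {
    Vinv <- tryCatch(solve(eg$vectors), error = function(e) NULL)
    if (!is.null(Vinv)) {
      Pe <- Re(eg$vectors %*% (exp(eg$values * check_t) * Vinv))
      Pr <- expm_fallback(check_t)
      use_eigen <- max(abs(Pe - Pr)) < 1e-9
    }
  }
  if (!use_eigen) {
    return(expm_fallback)
  }
  V <- eg$vectors
  lam <- eg$values
  function(t) {
    P <- Re(V %*% (exp(lam * t) * Vinv))
    P[P < 0] <- 0
    P
  }
}

## Precompute the per-tree structures the pruning pass needs so that MCMC
## and grid integration do not re-derive them at every likelihood call.
prepare_pruning <- function(tree, data) {
  ntip <- length(tree$tip.label)
  missing_taxa <- setdiff(tree$tip.label, names(data$states))
  if (length(missing_taxa)) {
    stop(
      "taxa in tree absent from character data: ",
      paste(missing_taxa, collapse = ", ")
    )
  }
  po <- ape::reorder.phylo(tree, "postorder")
  k <- length(data$state_space)
  tip_idx <- data$states[tree$tip.label]
  tip_part <- matrix(1, ntip, k)
  obs <- !is.na(tip_idx)
  tip_part[obs, ] <- 0
  tip_part[cbind(which(obs), tip_idx[obs])] <- 1
  obs_counts <- tabulate(tip_idx[obs], nbins = k)
  list(
    edge = po$edge, lengths = po$edge.length, ntip = ntip,
    nnode = tree$Nnode, k = k, tip_part = tip_part,
    root = ntip + 1L, tip_freq = obs_counts
  )
}

## Core pruning pass: returns the root partial-likelihood vector together
## with the accumulated log scaling factor.
pruning_pass <- function(prep, Pfun) {
  k <- prep$k
  n_nodes <- prep$ntip + prep$nnode
  lik <- matrix(1, n_nodes, k)
  lik[seq_len(prep$ntip), ] <- prep$tip_part
  logscale <- 0
  edge <- prep$edge
  lens <- prep$lengths
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1L]
    chi <- edge[e, 2L]
    contrib <- Pfun(lens[e]) %*% lik[chi, ]
    row <- lik[par, ] * contrib
    m <- max(row)
    if (m > 0 && m < 1e-200) {
      row <- row / m
      logscale <- logscale + log(m)
    }
    lik[par, ] <- row
  }
  list(root_partial = lik[prep$root, ], logscale = logscale, lik = lik)
}

## Fast path used internally once a prep structure exists.
loglik_prepared <- function(prep, Pfun, root_freqs) {
  pass <- pruning_pass(prep, Pfun)
  s <- sum(root_freqs * pass$root_partial)
  if (s <= 0) {
    return(-Inf)
  }
  log(s) + pass$logscale
}

#' Log-likelihood of character data on a tree
#'
#' Felsenstein pruning: the log of the sum over root states of the root
#' weights times the product over branches of `exp(Q t)`, with missing tip
#' states contributing an all-ones partial likelihood.
#'
#' @param tree A `phylo`.
#' @param data A `character_data` covering all leaves (missing allowed).
#' @param Q A generator matrix over `data`'s state space.
#' @param root A [root_policy()] or a numeric root-frequency vector
#'   (default uniform).
#' @return The log-likelihood (scalar; `-Inf` when the data have zero
#'   probability under `Q`).
#' @export
tree_log_likelihood <- function(tree, data, Q,
                                root = root_policy("uniform")) {
  stopifnot(nrow(Q) == length(data$state_space))
  prep <- prepare_pruning(tree, data)
  Pfun <- transition_prob_fn(Q, check_t = max(prep$lengths, 1e-8))
  freqs <- resolve_root_freqs(root, prep$k, tip_freq = prep$tip_freq)
  loglik_prepared(prep, Pfun, freqs)
}

#' Log-likelihood averaged quantities over a tree sample
#'
#' Convenience wrapper: per-tree log-likelihoods for fixed `Q`.
#'
#' @param trees A `multiPhylo`.
#' @inheritParams tree_log_likelihood
#' @return Numeric vector of per-tree log-likelihoods.
#' @export
sample_log_likelihoods <- function(trees, data, Q,
                                   root = root_policy("uniform")) {
  vapply(
    trees,
    function(tr) tree_log_likelihood(tr, data, Q, root = root),
    numeric(1L)
  )
}
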