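# Independent oracles used across the suite.  They deliberately avoid the
# package's pruning / mapping code paths: transition probabilities come
# from a scaled Taylor-series exponential and likelihoods from explicit
# enumeration.  (ape::matexpo is not used: it silently returns wrong
# results for generators with complex eigenvalues.)

# Simple scaling-and-squaring Taylor exponential, independent of both
# Matrix::expm and the package's eigendecomposition path.
expm_series <- function(M) {
  j <- max(0L, ceiling(log2(max(1e-12, max(abs(M))))) + 2L)
  A <- M / 2^j
  S <- diag(nrow(M))
  term <- diag(nrow(M))
  for (i in 1:30) {
    term <- term %*% A / i
    S <- S + term
  }
  for (i in seq_len(j)) S <- S %*% S
  dimnames(S) <- NULL
  S
}

# Enumeration likelihood: sum over all assignments of states to internal
# nodes (and to missing tips) of root_freq * prod over edges P[s_par, s_chi].
brute_force_loglik <- function(tree, data, Q, root_freqs) {
  k <- nrow(Q)
  ntip <- length(tree$tip.label)
  n_nodes <- ntip + tree$Nnode
  P <- lapply(seq_len(nrow(tree$edge)), function(e) {
    expm_series(Q * tree$edge.length[e])
  })
  tip_idx <- data$states[tree$tip.label]
  free <- c(which(is.na(tip_idx)), (ntip + 1L):n_nodes)
  fixed <- setdiff(seq_len(ntip), free)
  grid <- do.call(expand.grid, rep(list(seq_len(k)), length(free)))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    assign <- integer(n_nodes)
    assign[fixed] <- tip_idx[fixed]
    assign[free] <- as.integer(grid[g, ])
    pr <- unname(root_freqs[assign[ntip + 1L]])
    for (e in seq_len(nrow(tree$edge))) {
      pr <- pr * P[[e]][assign[tree$edge[e, 1L]], assign[tree$edge[e, 2L]]]
      if (pr == 0) break
    }
    total <- total + pr
  }
  log(total)
}

# Root-state posterior by the same enumeration.
brute_force_root_posterior <- function(tree, data, Q, root_freqs) {
  k <- nrow(Q)
  ntip <- length(tree$tip.label)
  out <- numeric(k)
  for (s in seq_len(k)) {
    rf <- numeric(k)
    rf[s] <- root_freqs[s]
    out[s] <- exp(brute_force_loglik(tree, data, Q, rf))
  }
  out / sum(out)
}

# Random generator matrix with positive off-diagonals.
random_Q <- function(k, min = 0.2, max = 1.5) {
  Q <- matrix(stats::runif(k * k, min, max), k, k)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  dimnames(Q) <- list(as.character(seq_len(k)), as.character(seq_len(k)))
  Q
}

# Random character data over a tree's tips, optionally with missing tips.
random_data <- function(tree, k, p_missing = 0) {
  lab <- sample(as.character(seq_len(k)), length(tree$tip.label),
    replace = TRUE
  )
  if (p_missing > 0) {
    lab[stats::runif(length(lab)) < p_missing] <- NA
  }
  names(lab) <- tree$tip.label
  character_data(lab, as.character(seq_len(k)))
}

# Exhaustive minimum parsimony cost: try every full labeling.
brute_force_parsimony <- function(tree, data, costs) {
  k <- length(data$state_space)
  ntip <- length(tree$tip.label)
  n_nodes <- ntip + tree$Nnode
  tip_idx <- data$states[tree$tip.label]
  free <- c(which(is.na(tip_idx)), (ntip + 1L):n_nodes)
  fixed <- setdiff(seq_len(ntip), free)
  grid <- do.call(expand.grid, rep(list(seq_len(k)), length(free)))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    assign <- integer(n_nodes)
    assign[fixed] <- tip_idx[fixed]
    assign[free] <- as.integer(grid[g, ])
    cost <- sum(costs[cbind(
      assign[tree$edge[, 1L]],
      assign[tree$edge[, 2L]]
    )])
    best <- min(best, cost)
  }
  best
}

# A small fixed tree collection for parameterized likelihood tests.
oracle_trees <- function() {
  list(
    read_newick("((A:0.5,B:1.2):0.8,C:2);"),
    read_newick("((A:1,B:1):1,(C:1,D:1):1);"),
    read_newick("(((A:0.3,B:0.7):0.5,C:1.1):0.4,(D:0.9,E:0.2):0.6);"),
    read_newick("((A:1,(B:0.4,C:0.4):0.6):0.5,((D:0.2,E:0.8):0.9,F:1.5):0.2);")
  )
}
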