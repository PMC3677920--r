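## Parsimony mapping: Fitch counts on binary trees, Sankoff dynamic
## programming under arbitrary nonnegative cost matrices (including
## Dollo-style prohibitive regain costs), and transition counting on a
## resolved ancestral labeling.

#' Cost matrix for Sankoff parsimony
#'
#' @param costs A k x k nonnegative numeric matrix with zero diagonal.
#' @param state_space Optional state labels (defaults to existing
#'   dimnames or `1..k`).
#' @return A validated cost matrix with dimnames.
#' @export
cost_matrix <- function(costs, state_space = NULL) {
  costs <- as.matrix(costs)
  stopifnot(nrow(costs) == ncol(costs))
  if (any(costs < 0)) stop("costs must be nonnegative")
  if (any(diag(costs) != 0)) stop("diagonal costs must be zero")
  if (is.null(state_space)) {
    state_space <- rownames(costs)
    if (is.null(state_space)) state_space <- as.character(seq_len(nrow(costs)))
  }
  dimnames(costs) <- list(state_space, state_space)
  costs
}

#' Dollo-style cost matrix forbidding regain of a complex state
#'
#' Losing the complex character state costs 1; regaining it carries a
#' prohibitive (large finite) cost, so reconstructions never infer
#' parallel gains.
#'
#' @param state_space Two state labels, the complex ("present") state
#'   first, e.g. `c("S+", "S-")`.
#' @param prohibitive The regain cost (default `1e6`).
#' @return A 2 x 2 cost matrix.
#' @export
dollo_costs <- function(state_space = c("S+", "S-"), prohibitive = 1e6) {
  stopifnot(length(state_space) == 2L)
  cost_matrix(
    matrix(c(0, 1, prohibitive, 0), 2L, 2L, byrow = TRUE),
    state_space
  )
}

#' Read / write a cost matrix as tab-delimited text
#' @param path File path.
#' @param costs A cost matrix.
#' @export
read_cost_tsv <- function(path) {
  m <- as.matrix(utils::read.delim(path,
    row.names = 1L, check.names = FALSE,
    comment.char = "#"
  ))
  cost_matrix(m, rownames(m))
}

#' @rdname read_cost_tsv
#' @export
write_cost_tsv <- function(costs, path) {
  utils::write.table(
    data.frame(state = rownames(costs), costs, check.names = FALSE),
    path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Fitch parsimony count of state changes
#'
#' Minimum number of unordered state changes over all ancestral labelings,
#' by the classic intersection/union down-pass.  Requires a binary tree
#' and complete data; use [sankoff()] for polytomies, missing tips or
#' asymmetric costs.
#'
#' @param tree A binary `phylo`.
#' @param data A `character_data` with no missing states.
#' @return Integer change count.
#' @export
fitch_count <- function(tree, data) {
  ntip <- length(tree$tip.label)
  if (tree$Nnode != ntip - 1L) {
    stop("fitch_count needs a binary tree; use sankoff() for polytomies")
  }
  idx <- data$states[tree$tip.label]
  if (anyNA(idx)) {
    stop("missing data: use sankoff() with expanded tip state sets")
  }
  k <- length(data$state_space)
  n_nodes <- ntip + tree$Nnode
  sets <- matrix(FALSE, n_nodes, k)
  sets[cbind(seq_len(ntip), idx)] <- TRUE
  po <- ape::reorder.phylo(tree, "postorder")
  changes <- 0L
  seen <- logical(n_nodes)
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1L]
    chi <- po$edge[e, 2L]
    if (!seen[par]) {
      sets[par, ] <- sets[chi, ]
      seen[par] <- TRUE
    } else {
      inter <- sets[par, ] & sets[chi, ]
      if (any(inter)) {
        sets[par, ] <- inter
      } else {
        sets[par, ] <- sets[par, ] | sets[chi, ]
        changes <- changes + 1L
      }
    }
  }
  changes
}

#' Sankoff parsimony under an arbitrary cost matrix
#'
#' Dynamic programming over the tree: for every node the minimal total
#' cost of the subtree given each node state, combined rootward.  Missing
#' tips receive an all-states (zero-cost) set.  Besides the minimum total
#' cost, the per-node sets of states attainable in *some* globally optimal
#' labeling are reported (via an up-pass), together with one deterministic
#' optimal labeling (ties broken toward the lower state index, assigned
#' root-down).
#'
#' @param tree A `phylo` (polytomies allowed).
#' @param data A `character_data`.
#' @param costs A [cost_matrix()] over the data's state space.
#' @return A list with `cost` (minimum total cost), `state_sets` (list of
#'   optimal state-label vectors per node, tips included), `labeling`
#'   (integer assignment per node for the tie-broken optimum) and
#'   `infeasible` (`TRUE` when the minimum cost is at or above the largest
#'   cost entry, signalling an all-prohibitive reconstruction).
#' @export
sankoff <- function(tree, data, costs) {
  k <- length(data$state_space)
  costs <- cost_matrix(costs, data$state_space)
  ntip <- length(tree$tip.label)
  n_nodes <- ntip + tree$Nnode
  idx <- data$states[tree$tip.label]
  S <- matrix(0, n_nodes, k) # down-pass subtree costs
  inf_cost <- sum(costs) * n_nodes + 1 # acts as +Inf but stays finite
  for (i in seq_len(ntip)) {
    if (!is.na(idx[i])) {
      S[i, ] <- inf_cost
      S[i, idx[i]] <- 0
    }
  }
  po <- ape::reorder.phylo(tree, "postorder")
  edge <- po$edge
  ## edge contribution child -> parent: E[par_state] = min_j C[par,j] + S[chi,j]
  econ <- matrix(0, nrow(edge), k)
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1L]
    chi <- edge[e, 2L]
    for (s in seq_len(k)) {
      econ[e, s] <- min(costs[s, ] + S[chi, ])
    }
    S[par, ] <- S[par, ] + econ[e, ]
  }
  root <- ntip + 1L
  min_cost <- min(S[root, ])
  prohibitive <- max(costs)
  infeasible <- prohibitive >= 1e5 && min_cost >= prohibitive
  ## up-pass: U[v, s] = cost of the rest of the tree if v has state s
  U <- matrix(0, n_nodes, k)
  children <- split(seq_len(nrow(edge)), edge[, 1L])
  cw_edges <- rev(seq_len(nrow(edge))) # rootward-first order
  for (e in cw_edges) {
    par <- edge[e, 1L]
    chi <- edge[e, 2L]
    sib_e <- setdiff(children[[as.character(par)]], e)
    base <- U[par, ]
    for (se in sib_e) base <- base + econ[se, ]
    for (s in seq_len(k)) {
      U[chi, s] <- min(base + costs[, s])
    }
  }
  total <- S + U
  state_sets <- lapply(seq_len(n_nodes), function(v) {
    data$state_space[which(abs(total[v, ] - min_cost) < 1e-9)]
  })
  ## deterministic single labeling, assigned root-down with low-index ties
  labeling <- integer(n_nodes)
  labeling[root] <- which.min(S[root, ])
  for (e in cw_edges) {
    par <- edge[e, 1L]
    chi <- edge[e, 2L]
    labeling[chi] <- which.min(costs[labeling[par], ] + S[chi, ])
  }
  list(
    cost = min_cost, state_sets = state_sets, labeling = labeling,
    infeasible = infeasible
  )
}

#' Count directed transitions on a fully labelled tree
#'
#' @param tree A `phylo`.
#' @param assignment Integer state per node (tips then internals), e.g.
#'   the `labeling` from [sankoff()].
#' @param from,to States (labels need `state_space`) delimiting the
#'   directed change counted on parent-to-child edges.
#' @param state_space Needed when `from`/`to` are labels.
#' @return Integer count.
#' @export
count_transitions <- function(tree, assignment, from, to,
                              state_space = NULL) {
  if (is.character(from)) {
    from <- match(from, state_space)
    to <- match(to, state_space)
    if (is.na(from) || is.na(to)) stop("unknown state label")
  }
  sum(assignment[tree$edge[, 1L]] == from &
    assignment[tree$edge[, 2L]] == to)
}
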