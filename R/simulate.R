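## Forward simulation of a character along a tree, and the
## character-history container shared with stochastic mapping.

#' Character history on a tree
#'
#' A piecewise-constant state assignment along every branch: for each edge
#' (in the tree's edge-matrix order) a named numeric vector of segment
#' lengths whose names are state labels, ordered rootward-to-tipward.
#' Segment lengths on an edge sum to the edge length; adjacent segments
#' differ in state; the final segment's state equals the child node's state.
#'
#' @param tree The `phylo` the history lives on.
#' @param node_states Integer vector of states at every node
#'   (tips first, then internals, as in the `phylo` numbering).
#' @param maps List of named numeric vectors, one per edge row.
#' @param state_space Ordered state labels.
#' @return An object of class `character_history`.
#' @export
character_history <- function(tree, node_states, maps, state_space) {
  stopifnot(length(maps) == nrow(tree$edge))
  structure(
    list(
      tree = tree, node_states = node_states, maps = maps,
      state_space = state_space
    ),
    class = "character_history"
  )
}

#' @export
print.character_history <- function(x, ...) {
  nchanges <- sum(vapply(x$maps, length, integer(1L)) - 1L)
  cat(
    "character_history:", length(x$tree$tip.label), "tips,",
    nchanges, "state change(s)\n"
  )
  invisible(x)
}

#' Number of state changes in a history
#' @param history A `character_history`.
#' @param from,to Optional state labels restricting the count to one
#'   directed change type.
#' @return Integer count of changes along all branches.
#' @export
history_changes <- function(history, from = NULL, to = NULL) {
  total <- 0L
  for (m in history$maps) {
    if (length(m) < 2L) next
    s <- names(m)
    a <- s[-length(s)]
    b <- s[-1L]
    keep <- rep(TRUE, length(a))
    if (!is.null(from)) keep <- keep & a == from
    if (!is.null(to)) keep <- keep & b == to
    total <- total + sum(keep)
  }
  total
}

#' Tip states implied by a history
#' @param history A `character_history`.
#' @return A `character_data` over the tree's tips.
#' @export
history_tip_states <- function(history) {
  ntip <- length(history$tree$tip.label)
  idx <- history$node_states[seq_len(ntip)]
  names(idx) <- history$tree$tip.label
  character_data(idx, state_space = history$state_space)
}

#' Fraction of total tree length spent in each state
#'
#' @param history A `character_history`.
#' @return Named numeric vector over the state space, summing to 1
#'   (all zeros if the tree has zero total length).
#' @export
dwell_fractions <- function(history) {
  tot <- stats::setNames(numeric(length(history$state_space)),
                         history$state_space)
  for (m in history$maps) {
    agg <- tapply(m, names(m), sum)
    tot[names(agg)] <- tot[names(agg)] + agg
  }
  s <- sum(tot)
  if (s > 0) tot / s else tot
}

## Simulate one branch forward from `state` for duration `t`.
## Returns a named numeric segment vector (names = state labels).
simulate_branch <- function(state, t, Q, state_space) {
  k <- nrow(Q)
  segs <- numeric(0L)
  labs <- character(0L)
  remaining <- t
  s <- state
  repeat {
    rate <- -Q[s, s]
    if (rate <= 0) {
      segs <- c(segs, remaining)
      labs <- c(labs, state_space[s])
      break
    }
    wait <- stats::rexp(1L, rate)
    if (wait >= remaining) {
      segs <- c(segs, remaining)
      labs <- c(labs, state_space[s])
      break
    }
    segs <- c(segs, wait)
    labs <- c(labs, state_space[s])
    remaining <- remaining - wait
    p <- Q[s, ]
    p[s] <- 0
    s <- sample.int(k, 1L, prob = p)
  }
  names(segs) <- labs
  segs
}

#' Simulate a character down a tree
#'
#' Draws the root state from the root policy, then evolves the character
#' along every branch with exponential waiting times (rate `-Q[s,s]`) and
#' jump probabilities proportional to the off-diagonal generator row.
#'
#' @param tree A `phylo`.
#' @param Q A generator matrix with state labels as dimnames.
#' @param root A [root_policy()] or numeric root-frequency vector.
#' @param seed Optional integer seed for reproducibility.
#' @return A list with `data` (tip `character_data`) and `history`
#'   (the full `character_history`).
#' @export
simulate_character <- function(tree, Q, root = root_policy("uniform"),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(Q)
  state_space <- rownames(Q)
  if (is.null(state_space)) state_space <- as.character(seq_len(k))
  ntip <- length(tree$tip.label)
  n_nodes <- ntip + tree$Nnode
  freqs <- resolve_root_freqs(root, k)
  node_states <- integer(n_nodes)
  root_id <- ntip + 1L
  node_states[root_id] <- sample.int(k, 1L, prob = freqs)
  cw <- ape::reorder.phylo(tree, "cladewise")
  maps <- vector("list", nrow(tree$edge))
  ## map rows of the cladewise edge matrix back to the original edge order
  orig_key <- paste(tree$edge[, 1L], tree$edge[, 2L])
  for (e in seq_len(nrow(cw$edge))) {
    par <- cw$edge[e, 1L]
    chi <- cw$edge[e, 2L]
    seg <- simulate_branch(node_states[par], cw$edge.length[e], Q, state_space)
    node_states[chi] <- match(names(seg)[length(seg)], state_space)
    maps[[match(paste(par, chi), orig_key)]] <- seg
  }
  hist <- character_history(tree, node_states, maps, state_space)
  list(data = history_tip_states(hist), history = hist)
}

#' Project a history onto a component character
#'
#' Renames every segment state through `mapping` (e.g. joint `S+B-` to
#' component `S+`) and merges adjacent segments that become identical, so
#' a joint-character history yields the implied single-character history.
#'
#' @param history A `character_history`.
#' @param mapping Named character vector: `mapping[old_state] = new_state`.
#' @param state_space Ordered state space of the projected character.
#' @return A `character_history` over `state_space`.
#' @export
history_project <- function(history, mapping, state_space) {
  maps <- lapply(history$maps, function(m) {
    labs <- unname(mapping[names(m)])
    keep_seg <- numeric(0L)
    keep_lab <- character(0L)
    for (i in seq_along(m)) {
      if (length(keep_lab) && keep_lab[length(keep_lab)] == labs[i]) {
        keep_seg[length(keep_seg)] <- keep_seg[length(keep_seg)] + m[i]
      } else {
        keep_seg <- c(keep_seg, m[i])
        keep_lab <- c(keep_lab, labs[i])
      }
    }
    stats::setNames(keep_seg, keep_lab)
  })
  node_states <- match(
    unname(mapping[history$state_space[history$node_states]]),
    state_space
  )
  character_history(history$tree, node_states, maps, state_space)
}

#' Tabulate a history as per-branch segments
#'
#' @param history A `character_history`.
#' @return A data frame with columns `edge`, `parent`, `child`, `segment`,
#'   `state`, `length` (segments ordered rootward-to-tipward).
#' @export
history_segments <- function(history) {
  edge <- history$tree$edge
  rows <- lapply(seq_along(history$maps), function(e) {
    m <- history$maps[[e]]
    data.frame(
      edge = e, parent = edge[e, 1L], child = edge[e, 2L],
      segment = seq_along(m), state = names(m), length = unname(m)
    )
  })
  do.call(rbind, rows)
}

#' @rdname history_segments
#' @param path Output path for the tab-delimited segment table.
#' @export
write_history_tsv <- function(history, path) {
  utils::write.table(history_segments(history), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
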