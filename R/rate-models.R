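#' Constrained k-state rate model templates
#'
#' A rate model is a k x k template over the off-diagonal entries of a
#' continuous-time Markov generator.  Each entry is either the structural
#' zero `0` or a parameter slot `1..n_params`; slots sharing an index share
#' one free rate (equality constraints).  The diagonal is implied (negative
#' row sums).  A root policy says how the root state is weighted when the
#' likelihood is summed over root states.
#'
#' @param template Integer k x k matrix; off-diagonals in `{0, 1..n}`,
#'   diagonal ignored.  Parameter indices must cover `1..n` contiguously.
#' @param state_space Ordered state labels of length k.
#' @param root_policy A [root_policy()] object (default uniform).
#' @param name Optional model name used in reports.
#' @return An object of class `rate_model_spec`.
#' @export
rate_model_spec <- function(template, state_space,
                            root_policy = coevotraits::root_policy("uniform"),
                            name = NULL) {
  template <- as.matrix(template)
  k <- length(state_space)
  stopifnot(nrow(template) == k, ncol(template) == k, k >= 2L)
  storage.mode(template) <- "integer"
  diag(template) <- NA_integer_
  off <- template[!is.na(template)]
  if (any(off < 0L)) stop("template entries must be >= 0")
  n_params <- max(off, 0L)
  if (n_params < 1L) stop("model needs at least one free rate")
  if (!setequal(seq_len(n_params), off[off > 0L])) {
    stop("parameter indices must be contiguous 1..n_params")
  }
  if (identical(root_policy$type, "fixed") &&
    (root_policy$state < 1L || root_policy$state > k)) {
    stop("fixed root state out of range")
  }
  dimnames(template) <- list(state_space, state_space)
  structure(
    list(
      k = k, template = template, n_params = n_params,
      state_space = state_space, root_policy = root_policy,
      name = if (is.null(name)) "custom" else name
    ),
    class = "rate_model_spec"
  )
}

#' @export
print.rate_model_spec <- function(x, ...) {
  cat(
    "rate_model_spec '", x$name, "': k = ", x$k, ", ",
    x$n_params, " free rate(s), root ", format_root_policy(x$root_policy),
    "\n",
    sep = ""
  )
  print(x$template)
  invisible(x)
}

#' Root-state weighting policy
#'
#' @param type One of `"uniform"` (equal weight on every state),
#'   `"fixed"` (all weight on one state) or `"empirical"` (weights equal to
#'   the observed tip-state frequencies).
#' @param state For `"fixed"`: the state, as label or 1-based index.
#' @param state_space Needed to resolve a label for `"fixed"`.
#' @return A list with class `root_policy`.
#' @export
root_policy <- function(type = c("uniform", "fixed", "empirical"),
                        state = NULL, state_space = NULL) {
  type <- match.arg(type)
  idx <- NULL
  if (type == "fixed") {
    if (is.null(state)) stop("fixed root policy needs a state")
    if (is.character(state)) {
      if (is.null(state_space)) stop("state_space needed to resolve label")
      idx <- match(state, state_space)
      if (is.na(idx)) stop("unknown root state: ", state)
    } else {
      idx <- as.integer(state)
    }
  }
  structure(list(type = type, state = idx), class = "root_policy")
}

format_root_policy <- function(p) {
  if (p$type == "fixed") paste0("fixed(", p$state, ")") else p$type
}

## Resolve a root policy (or a bare probability vector) to root-state
## frequencies of length k.  `tip_freq` supplies the empirical frequencies.
resolve_root_freqs <- function(policy, k, tip_freq = NULL) {
  if (is.numeric(policy)) {
    stopifnot(length(policy) == k, all(policy >= 0), sum(policy) > 0)
    return(policy / sum(policy))
  }
  switch(policy$type,
    uniform = rep(1 / k, k),
    fixed = {
      p <- numeric(k)
      p[policy$state] <- 1
      p
    },
    empirical = {
      if (is.null(tip_freq)) stop("empirical root policy needs tip data")
      tip_freq / sum(tip_freq)
    },
    stop("unknown root policy")
  )
}

## ---- Predefined model constants ------------------------------------------

#' State spaces used by the harvestman trait models
#' @name state-spaces
#' @return Character vectors of state labels.
#' @export
male_states <- function() c("S+P-", "S-P-", "S-P+")

#' @rdname state-spaces
#' @export
sb_states <- function() c("S+B-", "S+B+", "S-B+", "S-B-")

#' Predefined trait-evolution models
#'
#' The five model structures compared in the harvestman analysis:
#' \describe{
#'   \item{`male_6rate()`}{3 male states (`S+P-`, `S-P-`, `S-P+`), all six
#'     directed transitions free ("no precedence"); root uniform or fixed.}
#'   \item{`male_2rate()`}{only sac loss `S+P- -> S-P-` and pedipalp gain
#'     `S-P- -> S-P+` allowed ("penis precedence").}
#'   \item{`indep_4rate()`}{4 joint penis/barrier states; penis gain/loss
#'     rates shared across barrier states and vice versa; dual
#'     (two-characters-at-once) transitions are structural zeros.}
#'   \item{`dep_8rate()`}{all eight single-step transitions free
#'     ("dependent, precedence possible").}
#'   \item{`dep_7rate_noprec()`}{as `dep_8rate()` but barrier gain
#'     `S+B- -> S+B+` and sac loss `S+B- -> S-B-` share one rate
#'     ("dependent, no precedence").}
#' }
#'
#' @param root A [root_policy()]; `male_6rate()` also accepts the shorthand
#'   `"fixed"` for a root fixed at the sacculate state `S+P-`.
#' @return A `rate_model_spec`.
#' @name model-constants
NULL

#' @rdname model-constants
#' @export
male_6rate <- function(root = root_policy("uniform")) {
  if (identical(root, "fixed")) {
    root <- root_policy("fixed", "S+P-", male_states())
  }
  tpl <- matrix(0L, 3L, 3L)
  tpl[row(tpl) != col(tpl)] <- 0L
  idx <- 0L
  for (i in 1:3) {
    for (j in 1:3) {
      if (i != j) {
        idx <- idx + 1L
        tpl[i, j] <- idx
      }
    }
  }
  rate_model_spec(tpl, male_states(),
    root_policy = root,
    name = if (root$type == "fixed") "male_6rate_fixedroot" else "male_6rate"
  )
}

#' @rdname model-constants
#' @export
male_2rate <- function(root = root_policy("uniform")) {
  tpl <- matrix(0L, 3L, 3L)
  tpl[1L, 2L] <- 1L # S+P- -> S-P- (sac loss)
  tpl[2L, 3L] <- 2L # S-P- -> S-P+ (pedipalp enhancement)
  rate_model_spec(tpl, male_states(), root_policy = root, name = "male_2rate")
}

#' @rdname model-constants
#' @export
indep_4rate <- function(root = root_policy("uniform")) {
  tpl <- matrix(0L, 4L, 4L)
  ## params: 1 = S loss, 2 = S gain, 3 = B gain, 4 = B loss
  tpl[1L, 4L] <- 1L # S+B- -> S-B-
  tpl[2L, 3L] <- 1L # S+B+ -> S-B+
  tpl[4L, 1L] <- 2L # S-B- -> S+B-
  tpl[3L, 2L] <- 2L # S-B+ -> S+B+
  tpl[1L, 2L] <- 3L # S+B- -> S+B+
  tpl[4L, 3L] <- 3L # S-B- -> S-B+
  tpl[2L, 1L] <- 4L # S+B+ -> S+B-
  tpl[3L, 4L] <- 4L # S-B+ -> S-B-
  rate_model_spec(tpl, sb_states(), root_policy = root, name = "indep_4rate")
}

#' @rdname model-constants
#' @export
dep_8rate <- function(root = root_policy("uniform")) {
  tpl <- matrix(0L, 4L, 4L)
  single <- rbind(
    c(1L, 2L), c(1L, 4L), c(2L, 1L), c(2L, 3L),
    c(3L, 2L), c(3L, 4L), c(4L, 1L), c(4L, 3L)
  )
  tpl[single] <- seq_len(8L)
  rate_model_spec(tpl, sb_states(), root_policy = root, name = "dep_8rate")
}

#' @rdname model-constants
#' @export
dep_7rate_noprec <- function(root = root_policy("uniform")) {
  tpl <- dep_8rate()$template
  tpl[is.na(tpl)] <- 0L
  ## barrier gain (S+B- -> S+B+) and sac loss (S+B- -> S-B-) share rate 1
  tpl[1L, 2L] <- 1L
  tpl[1L, 4L] <- 1L
  ## recompact remaining indices to 2..7 in row-major order
  pos <- which(t(tpl) > 0L & !(t(row(tpl)) == 1L & t(col(tpl)) %in% c(2L, 4L)))
  nxt <- 2L
  for (i in 1:4) {
    for (j in 1:4) {
      if (i == 1L && j %in% c(2L, 4L)) next
      if (tpl[i, j] > 0L) {
        tpl[i, j] <- nxt
        nxt <- nxt + 1L
      }
    }
  }
  rate_model_spec(tpl, sb_states(), name = "dep_7rate_noprec")
}

## ---- Generator construction ----------------------------------------------

#' Instantiate a generator matrix from a model template
#'
#' @param spec A `rate_model_spec`.
#' @param rates Positive numeric vector of length `spec$n_params`.
#' @return A k x k generator matrix `Q` (off-diagonals >= 0, rows sum to 0),
#'   labelled by the state space.
#' @export
build_generator <- function(spec, rates) {
  stopifnot(inherits(spec, "rate_model_spec"))
  if (length(rates) != spec$n_params) {
    stop(
      "expected ", spec$n_params, " rates, got ", length(rates)
    )
  }
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    stop("rates must be positive and finite")
  }
  tpl <- spec$template
  Q <- matrix(0, spec$k, spec$k, dimnames = dimnames(tpl))
  sel <- !is.na(tpl) & tpl > 0L
  Q[sel] <- rates[tpl[sel]]
  diag(Q) <- -rowSums(Q)
  Q
}

#' Index of the rate parameter governing a transition
#'
#' @param spec A `rate_model_spec`.
#' @param from,to State labels or 1-based indices.
#' @return The parameter slot index, or 0 for a structural zero.
#' @export
rate_index <- function(spec, from, to) {
  if (is.character(from)) from <- match(from, spec$state_space)
  if (is.character(to)) to <- match(to, spec$state_space)
  if (is.na(from) || is.na(to)) stop("unknown state label")
  v <- spec$template[from, to]
  if (is.na(v)) stop("diagonal entries are not parameters")
  v
}

#' Embed two binary models as one independent 4-state model
#'
#' The joint state space follows the `(a1b1, a1b2, a2b2, a2b1)` cycle used
#' by [joint_character()].  Single-character transitions inherit the input
#' parameter slots (character A's slots first), dual transitions are
#' structural zeros.  The joint likelihood under this embedding factorizes
#' exactly into the product of the two marginal likelihoods.
#'
#' @param specA,specB Binary `rate_model_spec` objects.
#' @return A 4-state `rate_model_spec` with
#'   `n_params = n_params(A) + n_params(B)`.
#' @export
joint_embedding <- function(specA, specB) {
  if (specA$k != 2L || specB$k != 2L) stop("both specs must be binary")
  tplA <- specA$template
  tplB <- specB$template
  offB <- specA$n_params
  tpl <- matrix(0L, 4L, 4L)
  ## joint index of (a, b): (1,1)=1 (1,2)=2 (2,2)=3 (2,1)=4
  jidx <- matrix(c(1L, 2L, 4L, 3L), 2L, 2L, byrow = TRUE)
  for (a in 1:2) {
    for (b in 1:2) {
      here <- jidx[a, b]
      a2 <- 3L - a
      b2 <- 3L - b
      if (!is.na(tplA[a, a2]) && tplA[a, a2] > 0L) {
        tpl[here, jidx[a2, b]] <- tplA[a, a2]
      }
      if (!is.na(tplB[b, b2]) && tplB[b, b2] > 0L) {
        tpl[here, jidx[a, b2]] <- offB + tplB[b, b2]
      }
    }
  }
  rate_model_spec(tpl, joint_state_space(specA$state_space, specB$state_space),
    name = paste0("joint(", specA$name, ",", specB$name, ")")
  )
}

#' Degrees of freedom between nested models
#'
#' The difference in free-parameter counts, used for the chi-square
#' reference distribution of the log-likelihood-ratio test.
#'
#' @param complex,simple `rate_model_spec` objects with
#'   `n_params(complex) >= n_params(simple)`.
#' @return Nonnegative integer.
#' @export
model_df <- function(complex, simple) {
  d <- complex$n_params - simple$n_params
  if (d < 0L) stop("'complex' has fewer parameters than 'simple'")
  d
}

## ---- Model spec serialization --------------------------------------------

#' Write / read a model spec as a plain-text config block
#'
#' The format is line-oriented: `k`, the state labels, the root policy and
#' one template row per line, so user-defined models can be stored beside
#' the built-in constants.
#'
#' @param spec A `rate_model_spec`.
#' @param path File path.
#' @return `read_model_spec()` returns a `rate_model_spec`.
#' @export
write_model_spec <- function(spec, path) {
  rp <- spec$root_policy
  lines <- c(
    paste0("name\t", spec$name),
    paste0("k\t", spec$k),
    paste0("states\t", paste(spec$state_space, collapse = "\t")),
    paste0(
      "root\t", rp$type,
      if (rp$type == "fixed") paste0("\t", rp$state) else ""
    ),
    vapply(seq_len(spec$k), function(i) {
      row <- spec$template[i, ]
      row[is.na(row)] <- 0L
      paste(c("row", row), collapse = "\t")
    }, character(1L))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  lines <- readLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keyed <- stats::setNames(fields, vapply(fields, `[[`, "", 1L))
  k <- as.integer(keyed$k[2L])
  states <- keyed$states[-1L]
  rp <- if (keyed$root[2L] == "fixed") {
    root_policy("fixed", as.integer(keyed$root[3L]))
  } else {
    root_policy(keyed$root[2L])
  }
  rows <- fields[vapply(fields, `[[`, "", 1L) == "row"]
  tpl <- do.call(rbind, lapply(rows, function(f) as.integer(f[-1L])))
  rate_model_spec(tpl, states, root_policy = rp, name = keyed$name[2L])
}
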