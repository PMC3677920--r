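#' Construct categorical character data
#'
#' A character is a mapping from taxon label to a state in a declared,
#' ordered state space.  Missing observations are allowed and coded `NA`
#' internally (`"?"` in files); a missing tip contributes an all-ones
#' partial likelihood.
#'
#' @param x Named character vector of state labels (names are taxa), or a
#'   named integer vector of 1-based state indices.  `NA` or `"?"` marks a
#'   missing state.
#' @param state_space Ordered character vector of state labels (k >= 2).
#'   Defaults to the sorted unique observed states.
#' @return An object of class `character_data`: a list with `states`
#'   (named integer indices, `NA` = missing) and `state_space`.
#' @export
character_data <- function(x, state_space = NULL) {
  if (is.null(names(x)) || anyDuplicated(names(x))) {
    stop("'x' must be named by unique taxon labels")
  }
  if (is.numeric(x)) {
    if (is.null(state_space)) stop("state_space required for index input")
    idx <- as.integer(x)
  } else {
    x <- stats::setNames(as.character(x), names(x))
    x[!is.na(x) & x == "?"] <- NA_character_
    if (is.null(state_space)) state_space <- sort(unique(x[!is.na(x)]))
    idx <- match(x, state_space)
    if (any(!is.na(x) & is.na(idx))) {
      bad <- unique(x[!is.na(x) & is.na(idx)])
      stop("states not in state space: ", paste(bad, collapse = ", "))
    }
  }
  k <- length(state_space)
  if (k < 2L) stop("state space needs k >= 2")
  if (any(idx < 1L | idx > k, na.rm = TRUE)) stop("state index out of range")
  names(idx) <- names(x)
  structure(list(states = idx, state_space = state_space),
    class = "character_data"
  )
}

#' @export
print.character_data <- function(x, ...) {
  cat(
    "character_data:", length(x$states), "taxa, states {",
    paste(x$state_space, collapse = ", "), "},",
    sum(is.na(x$states)), "missing\n"
  )
  invisible(x)
}

#' State labels of a character
#' @param data A `character_data`.
#' @return Named character vector of state labels (`NA` where missing).
#' @export
state_labels <- function(data) {
  out <- data$state_space[data$states]
  names(out) <- names(data$states)
  out
}

#' Read a tab-delimited character matrix
#'
#' Expected format: header `taxon<TAB>state`, one taxon per line, `"?"` for
#' missing.  Lines starting with `#` are comments.
#'
#' @param path File path.
#' @param state_space Optional explicit ordered state space.
#' @return A `character_data`.
#' @export
read_character_tsv <- function(path, state_space = NULL) {
  df <- utils::read.delim(path,
    header = TRUE, sep = "\t",
    comment.char = "#", colClasses = "character"
  )
  if (!all(c("taxon", "state") %in% names(df))) {
    stop("expected columns 'taxon' and 'state' in ", path)
  }
  x <- df$state
  names(x) <- df$taxon
  character_data(x, state_space = state_space)
}

#' Write a character matrix to tab-delimited text
#'
#' @param data A `character_data`.
#' @param path Output path.
#' @export
write_character_tsv <- function(data, path) {
  lab <- state_labels(data)
  lab[is.na(lab)] <- "?"
  df <- data.frame(taxon = names(lab), state = unname(lab))
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}

#' Combine two binary characters into one joint 4-state character
#'
#' Joint states are ordered `(a1b1, a1b2, a2b2, a2b1)` where `a1, a2` and
#' `b1, b2` are the two input state spaces in order.  With the package's
#' penis/barrier coding (`S+`,`S-` and `B-`,`B+`) this yields the
#' conventional ordering `S+B-, S+B+, S-B+, S-B-`.  A taxon missing either
#' component is missing in the joint character.
#'
#' @param a,b Binary `character_data` over the same taxa.
#' @return A 4-state `character_data`.
#' @export
joint_character <- function(a, b) {
  if (length(a$state_space) != 2L || length(b$state_space) != 2L) {
    stop("both characters must be binary")
  }
  if (!setequal(names(a$states), names(b$states))) {
    stop("characters cover different taxon sets")
  }
  taxa <- names(a$states)
  ib <- b$states[taxa]
  ia <- a$states
  space <- joint_state_space(a$state_space, b$state_space)
  ## map (ia, ib) -> joint index in the (1,1),(1,2),(2,2),(2,1) cycle
  jmap <- matrix(c(1L, 2L, 4L, 3L), 2L, 2L, byrow = TRUE)
  idx <- ifelse(is.na(ia) | is.na(ib), NA_integer_, jmap[cbind(ia, ib)])
  names(idx) <- taxa
  character_data(idx, state_space = space)
}

joint_state_space <- function(sa, sb) {
  c(
    paste0(sa[1L], sb[1L]), paste0(sa[1L], sb[2L]),
    paste0(sa[2L], sb[2L]), paste0(sa[2L], sb[1L])
  )
}

#' Split a joint 4-state character back into its binary components
#'
#' Inverse of [joint_character()].
#'
#' @param joint A 4-state `character_data` built by [joint_character()] (or
#'   with a state space following the same cyclic ordering).
#' @param state_spaces Optional list of the two binary state spaces; by
#'   default they are recovered from the joint labels positionally (first
#'   two characters / remainder), which works for the package's `S+B-`
#'   style labels.
#' @return A list of two binary `character_data` objects.
#' @export
split_joint_character <- function(joint, state_spaces = NULL) {
  if (length(joint$state_space) != 4L) stop("need a 4-state character")
  amap <- c(1L, 1L, 2L, 2L)
  bmap <- c(1L, 2L, 2L, 1L)
  if (is.null(state_spaces)) {
    sa <- unique(substr(joint$state_space, 1L, 2L))[1:2]
    sb <- unique(substring(joint$state_space, 3L))[1:2]
    ## restore declared order: a1 from joint state 1, a2 from joint state 3
    sa <- c(substr(joint$state_space[1L], 1L, 2L),
            substr(joint$state_space[3L], 1L, 2L))
    sb <- c(substring(joint$state_space[1L], 3L),
            substring(joint$state_space[2L], 3L))
  } else {
    sa <- state_spaces[[1L]]
    sb <- state_spaces[[2L]]
  }
  ia <- amap[joint$states]
  ib <- bmap[joint$states]
  names(ia) <- names(ib) <- names(joint$states)
  list(
    character_data(ia, state_space = sa),
    character_data(ib, state_space = sb)
  )
}
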