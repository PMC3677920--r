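#' @importFrom ape read.tree write.tree keep.tip node.depth.edgelength Ntip Nnode
NULL

#' Parse a rooted newick string
#'
#' Thin, validating wrapper around [ape::read.tree()].  Branch lengths are
#' optional in the input; missing lengths become 0 so that downstream code
#' can always assume a numeric `edge.length`.
#'
#' @param text A single newick string (terminating `;` optional for ape).
#' @return An object of class `phylo` passing [validate_tree()].
#' @export
read_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tr <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) NULL
  )
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("newick parse error in: ", substr(text, 1L, 60L))
  }
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0, nrow(tr$edge))
  tr$edge.length[is.na(tr$edge.length)] <- 0
  validate_tree(tr)
  tr
}

#' Serialize a tree to newick
#'
#' @param tree A `phylo` object.
#' @return A newick string.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}

#' Validate rooted-tree invariants
#'
#' Checks that `tree` is a rooted `phylo` with unique leaf labels and
#' nonnegative branch lengths; every non-root node must have exactly one
#' parent (guaranteed by the `phylo` edge matrix, but verified here).
#'
#' @param tree A `phylo` object.
#' @return `tree`, invisibly.  Errors on violation.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' tree")
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate leaf labels: ", paste(dup, collapse = ", "))
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    stop("negative branch lengths")
  }
  nnode <- ape::Ntip(tree) + tree$Nnode
  parent_count <- tabulate(tree$edge[, 2L], nbins = nnode)
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])
  if (length(root) != 1L) stop("tree must have exactly one root")
  if (any(parent_count[-root] != 1L)) stop("node with multiple parents")
  invisible(tree)
}

#' Construct a tree sample
#'
#' Bundles trees over one shared taxon set into a `multiPhylo` with
#' provenance attributes, the container used for posterior tree samples.
#'
#' @param trees A list of `phylo` objects or a `multiPhylo`.
#' @param burn_in Burn-in fraction already applied upstream (metadata only).
#' @param source Free-text provenance tag.
#' @return A `multiPhylo` with attributes `burn_in` and `source`.
#' @export
tree_sample <- function(trees, burn_in = NA_real_, source = NA_character_) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  stopifnot(length(trees) >= 1L)
  labs <- sort(trees[[1L]]$tip.label)
  for (i in seq_along(trees)) {
    validate_tree(trees[[i]])
    if (!identical(sort(trees[[i]]$tip.label), labs)) {
      stop("tree ", i, " has a different taxon set")
    }
  }
  structure(trees,
    class = "multiPhylo",
    burn_in = burn_in, source = source
  )
}

#' Read a tree sample from a newick file (one tree per line)
#'
#' @param path File path.
#' @inheritParams tree_sample
#' @return A `multiPhylo` tree sample.
#' @export
read_tree_sample <- function(path, burn_in = NA_real_, source = path) {
  trs <- ape::read.tree(path)
  if (inherits(trs, "phylo")) trs <- list(trs)
  trs <- lapply(trs, function(tr) {
    if (is.null(tr$edge.length)) tr$edge.length <- rep(0, nrow(tr$edge))
    tr
  })
  tree_sample(trs, burn_in = burn_in, source = source)
}

#' Write a tree sample to a newick file
#'
#' @param sample A `multiPhylo`.
#' @param path Output file path.
#' @export
write_tree_sample <- function(sample, path) {
  writeLines(vapply(sample, ape::write.tree, character(1L)), path)
  invisible(path)
}

#' Prune a tree to a set of taxa
#'
#' Drops all other leaves; resulting degree-2 internal nodes are collapsed
#' with branch lengths summed, so pairwise path lengths among the kept taxa
#' are unchanged (delegates to [ape::keep.tip()]).
#'
#' @param tree A `phylo`.
#' @param keep Character vector of leaf labels to retain (>= 2).
#' @return The pruned `phylo`.
#' @export
prune_to_taxa <- function(tree, keep) {
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown)) {
    stop("unknown taxa: ", paste(unknown, collapse = ", "))
  }
  if (length(keep) < 2L) stop("need at least 2 taxa to keep")
  ape::keep.tip(tree, keep)
}

#' Test whether a tree is ultrametric
#'
#' All root-to-leaf path lengths equal, up to a relative tolerance:
#' `max - min <= rel_tolerance * max`.  Path sums are accumulated root-down.
#'
#' @param tree A `phylo`.
#' @param rel_tolerance Relative tolerance (default `1e-6`).
#' @return Logical scalar.
#' @export
is_ultrametric_tree <- function(tree, rel_tolerance = 1e-6) {
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  mx <- max(depths)
  if (mx == 0) return(TRUE)
  (mx - min(depths)) <= rel_tolerance * mx
}

## Clade identity on rooted trees: the set of leaf labels descending from an
## internal node, keyed as a sorted, collapsed string.
clade_key <- function(labels) paste(sort(labels), collapse = "\r")

## All clades of a rooted tree (one per internal node), as keys.
## Includes the root-spanning set; callers drop it where required.
clade_keys <- function(tree) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  desc <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1L]
    chi <- po$edge[e, 2L]
    desc[[par]] <- c(desc[[par]], desc[[chi]])
  }
  vapply(desc[(ntip + 1L):(ntip + nnode)], clade_key, character(1L))
}

#' Does a tree satisfy a rooted backbone constraint?
#'
#' The constraint tree may contain polytomies; its branch lengths are
#' ignored.  Every resolved clade of the constraint (the leaf set under an
#' internal node that does not span all constraint leaves) must appear,
#' restricted to the shared taxa, as a clade of `tree`.
#'
#' @param tree A `phylo` whose leaf set contains the constraint's leaves.
#' @param constraint A `phylo`, possibly with polytomies.
#' @return Logical scalar.
#' @export
satisfies_backbone <- function(tree, constraint) {
  shared <- intersect(constraint$tip.label, tree$tip.label)
  if (length(setdiff(constraint$tip.label, tree$tip.label))) {
    stop("constraint contains taxa absent from the tree")
  }
  cl <- clade_keys(constraint)
  full <- clade_key(constraint$tip.label)
  cl <- setdiff(cl, full)
  if (!length(cl)) return(TRUE) # star constraint: no resolved clades
  target <- if (length(shared) < ape::Ntip(tree)) {
    prune_to_taxa(tree, shared)
  } else {
    tree
  }
  all(cl %in% clade_keys(target))
}

#' Filter a tree sample with a backbone constraint
#'
#' Keeps, in the original order, exactly the trees for which
#' [satisfies_backbone()] is true.
#'
#' @param sample A `multiPhylo`.
#' @param constraint A constraint `phylo` (polytomies allowed).
#' @return The filtered `multiPhylo`; a warning is issued if empty.
#' @export
filter_by_backbone <- function(sample, constraint) {
  ok <- vapply(sample, satisfies_backbone,
    logical(1L),
    constraint = constraint
  )
  if (!any(ok)) {
    warning("no tree satisfies the backbone constraint")
    out <- structure(list(), class = "multiPhylo")
  } else {
    out <- structure(unclass(sample)[ok], class = "multiPhylo")
  }
  attr(out, "burn_in") <- attr(sample, "burn_in")
  attr(out, "source") <- attr(sample, "source")
  attr(out, "n_input") <- length(sample)
  out
}

#' Maximum clade credibility tree of a sample
#'
#' Each clade's credibility is its frequency among the sampled trees; the
#' MCC tree is the member tree maximizing the product of its clades'
#' frequencies (ties broken by earliest sample index).  The returned tree
#' carries per-node clade frequencies in `node.label`.
#'
#' @param sample A `multiPhylo` with >= 1 tree.
#' @return A list with elements `tree` (the annotated MCC `phylo`),
#'   `index` (its position in the sample) and `clade_freq` (named numeric
#'   vector of clade frequencies, names are `;`-joined sorted leaf labels).
#' @export
max_clade_credibility <- function(sample) {
  stopifnot(length(sample) >= 1L)
  keys_per_tree <- lapply(sample, clade_keys)
  counts <- table(unlist(keys_per_tree))
  freq <- as.numeric(counts) / length(sample)
  names(freq) <- names(counts)
  scores <- vapply(
    keys_per_tree,
    function(k) sum(log(freq[k])),
    numeric(1L)
  )
  best <- which.max(scores) # which.max returns the first maximum
  tree <- sample[[best]]
  tree$node.label <- sprintf("%.4g", freq[keys_per_tree[[best]]])
  pretty <- gsub("\r", ";", names(freq), fixed = TRUE)
  out_freq <- freq
  names(out_freq) <- pretty
  list(tree = tree, index = best, clade_freq = out_freq)
}

## Pairwise leaf path-length matrix (used by tests and pruning checks).
#' Pairwise root-connected path lengths between leaves
#' @param tree A `phylo`.
#' @return A symmetric matrix of patristic distances, labelled by taxa.
#' @export
leaf_distances <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[order(rownames(d)), order(colnames(d)), drop = FALSE]
}
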