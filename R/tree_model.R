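# Tree plumbing on top of ape's "phylo": newick parsing/writing with a
# canonical child order, bipartition (split) algebra, and outgroup rooting.

#' Parse a newick tree
#'
#' @param text newick string.
#' @param universe optional taxon universe; leaf labels must be a subset.
#' @return an ape `phylo`.
#' @export
parse_newick <- function(text, universe = NULL) {
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("malformed newick: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("malformed newick: could not parse input")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf label: ",
         tr$tip.label[duplicated(tr$tip.label)][1L])
  if (!is.null(universe)) {
    extra <- setdiff(tr$tip.label, universe)
    if (length(extra))
      stop("leaf labels outside the taxon universe: ",
           paste(extra, collapse = ", "))
  }
  tr
}

#' Write a tree as canonical newick
#'
#' Children are ordered lexicographically by their smallest descendant leaf
#' so that the same topology always yields the same string.  Internal node
#' labels (e.g. support values) are preserved.
#'
#' @param tree a `phylo`.
#' @param canonical reorder children canonically (default `TRUE`).
#' @return newick string.
#' @export
write_newick <- function(tree, canonical = TRUE) {
  if (!canonical) return(ape::write.tree(tree))
  n <- length(tree$tip.label)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  labs <- tree$node.label
  build <- function(v) {
    if (v <= n) return(list(str = tree$tip.label[v], key = tree$tip.label[v]))
    ch <- lapply(kids[[as.character(v)]], build)
    keys <- vapply(ch, `[[`, "", "key")
    ord <- order(keys)
    lab <- if (!is.null(labs)) labs[v - n] else ""
    if (is.na(lab)) lab <- ""
    list(str = paste0("(", paste(vapply(ch[ord], `[[`, "", "str"),
                                 collapse = ","), ")", lab),
         key = min(keys))
  }
  root <- n + 1L
  paste0(build(root)$str, ";")
}

# descendant-tip index sets for every node, as a list indexed by node id
.node_tipsets <- function(tree) {
  n <- length(tree$tip.label)
  sets <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) sets[[i]] <- i
  edge <- stats::reorder(tree, "postorder")$edge
  for (i in seq_len(nrow(edge))) {  # postorder: children before parents
    p <- edge[i, 1L]; c <- edge[i, 2L]
    sets[[p]] <- c(sets[[p]], sets[[c]])
  }
  sets
}

#' Non-trivial bipartitions of a tree
#'
#' One split per internal edge, canonicalized over the taxon universe: the
#' reported side is the smaller one (ties broken lexicographically by the
#' concatenated labels).  Trivial splits (singletons, the full set) are
#' excluded.  Rooted and unrooted representations of the same topology give
#' the same set.
#'
#' @param tree a `phylo`.
#' @param universe taxon universe (default: the tree's leaves).
#' @return named list of character vectors (canonical sides); names are the
#'   split keys used throughout the package.
#' @export
bipartitions <- function(tree, universe = NULL) {
  universe <- sort(universe %||% tree$tip.label)
  if (length(setdiff(tree$tip.label, universe)))
    stop("tree has leaves outside the declared universe")
  n <- length(tree$tip.label)
  sets <- .node_tipsets(tree)
  out <- list()
  for (v in (n + 1L):(n + tree$Nnode)) {
    side <- sort(tree$tip.label[sets[[v]]])
    key <- split_key(side, universe)
    if (!is.null(key) && is.null(out[[key]]))
      out[[key]] <- attr(key, "side")
  }
  out
}

#' Canonical key of a leaf split
#'
#' @param side character vector of taxa on one side.
#' @param universe full taxon universe.
#' @return the canonical key string (with the canonical side as an
#'   attribute), or `NULL` for a trivial split.
#' @export
split_key <- function(side, universe) {
  side <- sort(unique(side))
  other <- sort(setdiff(universe, side))
  if (length(side) < 2L || length(other) < 2L) return(NULL)  # trivial
  a <- paste(side, collapse = "|"); b <- paste(other, collapse = "|")
  canon <- if (length(side) < length(other)) side
           else if (length(other) < length(side)) other
           else if (a <= b) side else other
  key <- paste(canon, collapse = "|")
  attr(key, "side") <- canon
  key
}

#' Canonical topology fingerprint
#'
#' Two trees over the same leaves have the same fingerprint iff their
#' unrooted topologies (bipartition sets) are identical.
#'
#' @param tree a `phylo`.
#' @param universe taxon universe.
#' @return a single string.
#' @export
topology_key <- function(tree, universe = NULL) {
  paste(sort(names(bipartitions(tree, universe))), collapse = ";")
}

#' Root a tree on an outgroup
#'
#' If the outgroup is resolvable to one side of an edge the tree is rooted
#' there; otherwise it is rooted on the edge minimizing the number of taxa
#' misplaced relative to the outgroup (with a warning).
#'
#' @param tree a `phylo`.
#' @param outgroup character vector of outgroup taxa (non-empty, proper
#'   subset of the leaves).
#' @return rooted `phylo`.
#' @export
reroot_on_outgroup <- function(tree, outgroup) {
  tips <- tree$tip.label
  if (!length(outgroup)) stop("outgroup is empty")
  if (!all(outgroup %in% tips))
    stop("outgroup taxa not in tree: ",
         paste(setdiff(outgroup, tips), collapse = ", "))
  if (length(outgroup) >= length(tips))
    stop("outgroup must be a proper subset of the leaves")
  if (length(outgroup) == 1L || ape::is.monophyletic(ape::unroot(tree), outgroup))
    return(ape::root(ape::unroot(tree), outgroup = outgroup,
                     resolve.root = TRUE))
  # outgroup not on one side of any edge: minimize paraphyly
  ut <- ape::unroot(tree)
  n <- length(tips)
  sets <- .node_tipsets(ut)
  best <- NULL; best_mis <- Inf
  for (v in seq_along(sets)) {
    if (v == n + 1L) next
    side <- ut$tip.label[sets[[v]]]
    mis <- min(length(setdiff(side, outgroup)) +
                 length(setdiff(outgroup, side)),
               length(setdiff(setdiff(tips, side), outgroup)) +
                 length(setdiff(outgroup, setdiff(tips, side))))
    if (mis < best_mis) { best_mis <- mis; best <- side }
  }
  warning("outgroup is not resolvable to one side of an edge; rooting on ",
          "the edge minimizing outgroup paraphyly (", best_mis,
          " taxa misplaced)")
  ape::root(ut, outgroup = best, resolve.root = TRUE)
}
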