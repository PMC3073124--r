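# Consensus trees over tree sets, and Bremer decay support.

.check_same_leaves <- function(trees) {
  ref <- sort(trees[[1L]]$tip.label)
  for (tr in trees[-1L])
    if (!identical(sort(tr$tip.label), ref))
      stop("trees do not share the same leaf set")
  ref
}

# build a (rooted-shape) phylo from a set of mutually compatible splits
.tree_from_splits <- function(splits, universe, labels = NULL) {
  n <- length(universe)
  sizes <- lengths(splits)
  ord <- order(-sizes)                 # big clades first: parents before kids
  splits <- splits[ord]
  if (!is.null(labels)) labels <- labels[ord]
  k <- length(splits)
  # node ids: tips 1..n, root n+1, split i -> n+1+i
  parent_of <- function(i) {           # smallest strict superset, else root
    best <- 0L; best_size <- Inf
    for (j in seq_len(k)) {
      if (j == i) next
      if (length(splits[[j]]) > length(splits[[i]]) &&
          all(splits[[i]] %in% splits[[j]]) &&
          length(splits[[j]]) < best_size) {
        best <- j; best_size <- length(splits[[j]])
      }
    }
    if (best == 0L) n + 1L else n + 1L + best
  }
  edges <- matrix(0L, 0L, 2L)
  for (i in seq_len(k))
    edges <- rbind(edges, c(parent_of(i), n + 1L + i))
  for (x in seq_along(universe)) {
    best <- 0L; best_size <- Inf
    for (j in seq_len(k))
      if (universe[x] %in% splits[[j]] &&
          length(splits[[j]]) < best_size) {
        best <- j; best_size <- length(splits[[j]])
      }
    p <- if (best == 0L) n + 1L else n + 1L + best
    edges <- rbind(edges, c(p, x))
  }
  tr <- structure(list(edge = edges, Nnode = k + 1L,
                       tip.label = universe,
                       node.label = c("", if (is.null(labels))
                         rep("", k) else labels)),
                  class = "phylo")
  stats::reorder(tr, "cladewise")
}

#' Strict consensus tree
#'
#' The tree containing exactly the bipartitions present in every input
#' tree, with polytomies where the trees disagree.
#'
#' @param trees a `multiPhylo` (or list of `phylo`) over the same leaves.
#' @return a `phylo` (polytomous where unresolved).
#' @export
strict_consensus <- function(trees) {
  if (!length(trees)) stop("empty tree set")
  universe <- .check_same_leaves(trees)
  keys <- lapply(trees, function(tr) bipartitions(tr, universe))
  common <- Reduce(intersect, lapply(keys, names))
  .tree_from_splits(keys[[1L]][common], universe)
}

#' Majority-rule consensus tree
#'
#' Splits occurring in more than `threshold` of the input trees, annotated
#' with their occurrence frequencies as node labels.
#'
#' @param trees a `multiPhylo` over the same leaves.
#' @param threshold inclusion threshold (fraction, `>= 0.5`); a split is
#'   kept when its frequency strictly exceeds it.
#' @return a `phylo` with node labels giving split frequencies, and
#'   attribute `frequencies` (data frame of split key and frequency).
#' @export
majority_rule <- function(trees, threshold = 0.5) {
  if (!length(trees)) stop("empty tree set")
  if (threshold < 0.5) stop("threshold below 0.5 can yield incompatible splits")
  universe <- .check_same_leaves(trees)
  all_splits <- lapply(trees, function(tr) bipartitions(tr, universe))
  counts <- table(unlist(lapply(all_splits, names)))
  freq <- as.numeric(counts) / length(trees)
  keep <- freq > threshold
  keys <- names(counts)[keep]
  sides <- list()
  for (sp in all_splits) for (k in intersect(names(sp), keys))
    if (is.null(sides[[k]])) sides[[k]] <- sp[[k]]
  tr <- .tree_from_splits(sides[keys], universe,
                          labels = sprintf("%.3f", freq[keep]))
  attr(tr, "frequencies") <- data.frame(split = keys,
                                        frequency = freq[keep])
  tr
}

#' Bremer decay support
#'
#' The decay index of a clade is the length of the shortest tree lacking
#' the clade minus the optimal length.  The default `"constraint"` method
#' runs a converse-constraint heuristic search (trees containing the
#' clade's bipartition are rejected during swapping); `"sweep"` uses
#' exhaustive enumeration up to a ceiling and is exact but limited to small
#' taxon sets.
#'
#' @param m a [char_matrix()].
#' @param result an `mp_search` from [heuristic_search()] or
#'   [branch_and_bound()].
#' @param clades list of character vectors (taxa on one side of each
#'   bipartition); defaults to every non-trivial split of the strict
#'   consensus of `result$trees`.
#' @param method `"constraint"` or `"sweep"`.
#' @param config a [search_config()] for the constrained searches.
#' @param sweep_max ceiling offset for the sweep method.
#' @return data frame of class `support_table`: `clade` (list column),
#'   `label`, `size`, `bremer`, `estimate` (`TRUE` when the value comes from
#'   a heuristic constrained search that may be incomplete, in which case
#'   the true decay can be smaller), `frequency` (occurrence in
#'   `result$trees`).
#' @export
bremer_support <- function(m, result, clades = NULL,
                           method = c("constraint", "sweep"),
                           config = search_config(replicates = 5L),
                           sweep_max = 10L) {
  method <- match.arg(method)
  universe <- sort(m$taxa)
  cons <- strict_consensus(result$trees)
  cons_splits <- bipartitions(cons, universe)
  if (is.null(clades)) clades <- cons_splits
  keys <- lapply(trees_list <- result$trees, function(tr)
    names(bipartitions(tr, universe)))
  if (method == "sweep") {
    enum <- enumerate_trees(m, ceiling = result$best_length + sweep_max)
    enum_keys <- lapply(enum$trees, function(tr)
      names(bipartitions(tr, universe)))
  }
  if (!length(clades)) {
    out <- data.frame(label = character(0), size = integer(0),
                      bremer = integer(0), estimate = logical(0),
                      frequency = numeric(0))
    out$clade <- I(list())
    class(out) <- c("support_table", "data.frame")
    return(out)
  }
  rows <- lapply(clades, function(clade) {
    key <- split_key(clade, universe)
    if (is.null(key)) stop("trivial clade cannot be scored")
    if (!any(vapply(keys, function(k) key %in% k, logical(1L))))
      stop("clade not present in any retained tree: ", key)
    freq <- mean(vapply(keys, function(k) key %in% k, logical(1L)))
    if (method == "constraint") {
      res <- heuristic_search(m, config = config,
                              forbid_clade = attr(key, "side"))
      k <- res$best_length - result$best_length
      lb <- TRUE   # heuristic constrained search: k may overestimate
    } else {
      without <- !vapply(enum_keys, function(kk) key %in% kk, logical(1L))
      if (!any(without))
        stop("sweep ceiling too low for clade ", key)
      k <- min(enum$lengths[without]) - result$best_length
      lb <- FALSE
    }
    data.frame(label = key, size = length(clade), bremer = as.integer(k),
               estimate = lb, frequency = freq)
  })
  out <- do.call(rbind, rows)
  out$clade <- I(unname(clades))
  class(out) <- c("support_table", "data.frame")
  out
}
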