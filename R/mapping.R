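# Synapomorphy mapping: assigning character-state changes to branches of a
# rooted tree under a chosen resolution of ambiguity.

# single-state assignment for one character under ACCTRAN- or DELTRAN-style
# tie-breaking; guaranteed to realize the character's minimum length
.resolve_states_on_tree <- function(tree, cost, accelerate) {
  n <- length(tree$tip.label)
  root <- n + 1L
  edge <- stats::reorder(tree, "postorder")$edge
  state <- integer(n + tree$Nnode)
  cand <- which(cost[root, ] == min(cost[root, ]))
  state[root] <- cand[1L] - 1L
  for (i in rev(seq_len(nrow(edge)))) {       # preorder
    p <- edge[i, 1L]; v <- edge[i, 2L]
    sp <- state[p]
    tot <- cost[v, ] + as.numeric(seq_len(ncol(cost)) - 1L != sp)
    opt <- which(tot == min(tot)) - 1L
    state[v] <- if (sp %in% opt) {
      if (accelerate && any(opt != sp)) {
        # accept a change high in the tree when an equally parsimonious
        # changing assignment exists (favors early gains + reversals)
        min(opt[opt != sp])
      } else sp
    } else min(opt)
    # DELTRAN keeps the parent state whenever possible, delaying changes
  }
  state
}

#' Map synapomorphies onto a tree
#'
#' Assigns character-state changes to branches of a rooted tree.  Under
#' `"acctran"` changes are placed as close to the root as an optimal
#' reconstruction allows (favoring reversals); under `"deltran"` as close
#' to the tips as possible (favoring parallelisms); `"unambiguous"` reports
#' only changes present in every most-parsimonious reconstruction.  Under a
#' single full resolution on a fully resolved tree, the number of mapped
#' changes equals the tree's parsimony length.
#'
#' @param tree rooted `phylo`; leaves must be matrix taxa.
#' @param m a [char_matrix()].
#' @param resolution `"acctran"`, `"deltran"`, or `"unambiguous"`.
#' @return data frame of class `synapomorphy_map`: one row per change with
#'   columns `node` (ape id of the branch's child node), `clade` (list of
#'   descendant taxa), `char`, `char_name`, `from`, `to`, `resolution`,
#'   `homoplastic` (character needs more steps than its minimum on this
#'   tree's matrix).  The tree is attached as attribute `tree`.
#' @export
map_synapomorphies <- function(tree, m,
                               resolution = c("acctran", "deltran",
                                              "unambiguous")) {
  resolution <- match.arg(resolution)
  if (!ape::is.rooted(tree)) stop("tree must be rooted (see reroot_on_outgroup)")
  n <- length(tree$tip.label)
  if (tree$Nnode < n - 1L && resolution != "unambiguous")
    warning("tree has polytomies; changes are mapped per resolved subtree")
  masks_all <- .tree_states(tree, m)
  bounds <- char_bounds(m)
  edge <- stats::reorder(tree, "postorder")$edge
  tipsets <- .node_tipsets(tree)
  rows <- list()
  for (j in seq_len(m$n_char)) {
    cost <- .sankoff_down(tree, masks_all[, j])
    steps <- min(cost[n + 1L, ])
    if (steps == 0) next
    homopl <- steps > bounds$min_steps[j]
    name <- if (!is.null(m$defs)) m$defs$name[j] else NA_character_
    if (resolution == "unambiguous") {
      up <- .sankoff_up(tree, cost)
      best <- min(cost[n + 1L, ])
      kids <- split(edge[, 2L], edge[, 1L])
      for (i in seq_len(nrow(edge))) {
        p <- edge[i, 1L]; v <- edge[i, 2L]
        # minimum total cost when p and v share a state: if it exceeds the
        # optimum, every MPR changes on this branch
        sibs <- setdiff(kids[[as.character(p)]], v)
        a <- .outside_cost(tree, cost, up, p, sibs)
        ns <- ncol(cost)
        # joint cost over (parent state, child state) pairs on this branch
        pair <- outer(a, cost[v, ], `+`) +
          (1 - diag(ns))                  # +1 where states differ
        if (min(pair[cbind(1:ns, 1:ns)]) > best) {  # no same-state MPR
          opt <- which(pair == best, arr.ind = TRUE)
          rows[[length(rows) + 1L]] <- data.frame(
            node = v, char = j, char_name = name,
            from = paste(sort(unique(opt[, 1L])) - 1L, collapse = "/"),
            to = paste(sort(unique(opt[, 2L])) - 1L, collapse = "/"),
            resolution = resolution, homoplastic = homopl)
        }
      }
    } else {
      st <- .resolve_states_on_tree(tree, cost,
                                    accelerate = resolution == "acctran")
      for (i in seq_len(nrow(edge))) {
        p <- edge[i, 1L]; v <- edge[i, 2L]
        if (st[p] != st[v])
          rows[[length(rows) + 1L]] <- data.frame(
            node = v, char = j, char_name = name,
            from = as.character(st[p]), to = as.character(st[v]),
            resolution = resolution, homoplastic = homopl)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(node = integer(0), char = integer(0),
               char_name = character(0), from = character(0),
               to = character(0), resolution = character(0),
               homoplastic = logical(0))
  out$clade <- I(lapply(out$node, function(v)
    sort(tree$tip.label[tipsets[[v]]])))
  attr(out, "tree") <- tree
  class(out) <- c("synapomorphy_map", "data.frame")
  out
}

# cost of the whole tree minus the subtree of child v, conditional on the
# parent p's state (edge into v NOT charged): up[p] plus sibling folds
.outside_cost <- function(tree, cost, up, p, sibs) {
  a <- up[p, ]
  for (w in sibs) a <- a + pmin(cost[w, ], min(cost[w, ]) + 1)
  a
}

#' Diagnostic changes on a clade's stem branch
#'
#' @param map a [map_synapomorphies()] result.
#' @param clade character vector of taxa forming the clade.
#' @return the rows of `map` on the clade's stem branch.
#' @export
clade_diagnostics <- function(map, clade) {
  tree <- attr(map, "tree")
  clade <- sort(clade)
  hit <- vapply(seq_len(nrow(map)), function(i)
    identical(map$clade[[i]], clade), logical(1L))
  if (!any(hit)) {
    # the clade may exist with no stem changes; verify it is in the tree
    tipsets <- .node_tipsets(tree)
    present <- any(vapply(tipsets, function(s)
      identical(sort(tree$tip.label[s]), clade), logical(1L)))
    if (!present) stop("clade not present in the mapped tree")
  }
  map[hit, , drop = FALSE]
}
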