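# Parsimony scoring: tree length under unordered (Fitch) costs, per-character
# bounds, ensemble consistency/retention indices, and ancestral state-set
# reconstruction.

# states matrix (taxa x char bitmasks) reordered to a tree's tip order
.tree_states <- function(tree, m) {
  idx <- match(tree$tip.label, m$taxa)
  if (anyNA(idx))
    stop("tree leaves without a matrix row: ",
         paste(tree$tip.label[is.na(idx)], collapse = ", "))
  m$states[idx, , drop = FALSE]
}

.is_binary_unrooted <- function(tree) {
  n <- length(tree$tip.label)
  tree$Nnode == n - 2L
}

#' Parsimony length of a tree
#'
#' Minimum number of unordered state changes summed over characters, exact
#' for ambiguous/polymorphic cells and (via unit-cost dynamic programming)
#' for polytomies.  The length is invariant to rooting.
#'
#' @param tree a `phylo`; leaves must be a subset of the matrix taxa.
#' @param m a [char_matrix()].
#' @param engine `"sankoff"` (default; any tree shape), `"bitset"` (the
#'   search engine's bit-set Fitch path; binary trees), or `"scalar"` (a
#'   plain per-character R implementation of the Fitch passes; binary
#'   trees).  All three agree on binary trees.
#' @return list with `total` (integer) and, for the sankoff and scalar
#'   engines, `per_char` (integer vector of per-character steps).
#' @export
fitch_length <- function(tree, m, engine = c("sankoff", "bitset", "scalar")) {
  engine <- match.arg(engine)
  st <- .tree_states(tree, m)
  if (engine == "sankoff") {
    res <- cpp_score_sankoff(tree$edge, length(tree$tip.label), st, MAX_STATES)
    return(list(total = as.integer(res$total),
                per_char = as.integer(res$per_char)))
  }
  ut <- if (.is_binary_unrooted(tree)) tree else ape::unroot(tree)
  if (!.is_binary_unrooted(ut))
    stop("engine '", engine, "' requires a binary tree")
  st <- .tree_states(ut, m)
  if (engine == "bitset")
    return(list(total = cpp_fitch_bitset(ut$edge, length(ut$tip.label), st),
                per_char = NULL))
  per <- vapply(seq_len(ncol(st)), function(j) .fitch_scalar(ut, st[, j]),
                integer(1L))
  list(total = sum(per), per_char = per)
}

# reference scalar Fitch down-pass for one character on a binary tree
.fitch_scalar <- function(tree, masks) {
  n <- length(tree$tip.label)
  sets <- integer(n + tree$Nnode)
  sets[seq_len(n)] <- masks
  steps <- 0L
  edge <- stats::reorder(tree, "postorder")$edge
  for (i in seq_len(nrow(edge))) {
    p <- edge[i, 1L]; c <- edge[i, 2L]
    if (sets[p] == 0L) { sets[p] <- sets[c]; next }
    x <- bitwAnd(sets[p], sets[c])
    if (x > 0L) sets[p] <- x
    else { sets[p] <- bitwOr(sets[p], sets[c]); steps <- steps + 1L }
  }
  steps
}

#' Per-character step bounds
#'
#' For each character: the minimum conceivable steps on any tree (number of
#' distinct determinate states minus one, floored at zero) and the maximum
#' steps, i.e. the length on the completely unresolved star tree, minimized
#' over the central state.  A cell with an uncertainty set costs nothing
#' when its set covers the central state; in particular `?`/`-` cells
#' (which resolve to all observed states) never contribute to either bound,
#' while an explicit uncertainty pair excluding the modal state adds one
#' step to the maximum.  A character with no determinate observations
#' contributes zero to both.
#'
#' @param m a [char_matrix()].
#' @return data frame with columns `char`, `min_steps`, `max_steps`.
#' @export
char_bounds <- function(m) {
  kinds <- cell_kinds(m)
  mm <- integer(m$n_char); gg <- integer(m$n_char)
  for (j in seq_len(m$n_char)) {
    det <- kinds[, j] == "determinate"
    tab <- table(m$symbols[det, j])
    mm[j] <- max(0L, length(tab) - 1L)
    if (length(tab) == 0L) { gg[j] <- 0L; next }
    masks <- m$states[, j]
    gg[j] <- min(vapply(0:(MAX_STATES - 1L), function(s)
      sum(bitwAnd(masks, bitwShiftL(1L, s)) == 0L), integer(1L)))
  }
  data.frame(char = seq_len(m$n_char), min_steps = mm, max_steps = gg)
}

#' Ensemble consistency and retention indices
#'
#' CI = M/S and RI = (G - S)/(G - M), where S is the observed tree length
#' and M, G are the sums of per-character minimum and maximum (star-tree)
#' steps.  Both the all-characters and the informative-only variants are
#' reported; `variant` selects which one populates the headline fields.
#'
#' @param S observed tree length (steps).
#' @param m a [char_matrix()].
#' @param variant `"all"` (default) or `"informative"`.
#' @param per_char optional per-character observed steps (required for the
#'   informative-only variant's S).
#' @return object of class `ensemble_indices`: list with `S`, `M`, `G`,
#'   `CI`, `RI`, `RC`, `variant`, `flags`, and `both` (a data frame with
#'   one row per variant).
#' @export
ensemble_indices <- function(S, m, variant = c("all", "informative"),
                             per_char = NULL) {
  variant <- match.arg(variant)
  b <- char_bounds(m)
  info <- informative_characters(m)
  one <- function(keep, S_keep) {
    M <- sum(b$min_steps[keep]); G <- sum(b$max_steps[keep])
    flags <- character(0)
    CI <- if (S_keep == 0) { flags <- c(flags, "S=0: CI undefined, reported as 1"); 1 }
          else M / S_keep
    RI <- if (G == M) { flags <- c(flags, "G=M: RI undefined"); NA_real_ }
          else (G - S_keep) / (G - M)
    list(S = S_keep, M = M, G = G, CI = CI, RI = RI, RC = CI * RI,
         flags = flags)
  }
  all_v <- one(seq_len(m$n_char), S)
  info_v <- if (is.null(per_char)) NULL
            else one(info, sum(per_char[info]))
  main <- if (variant == "all") all_v else {
    if (is.null(info_v))
      stop("per_char steps are required for the informative-only variant")
    info_v
  }
  both <- data.frame(
    variant = c("all", if (!is.null(info_v)) "informative"),
    S = c(all_v$S, info_v$S), M = c(all_v$M, info_v$M),
    G = c(all_v$G, info_v$G),
    CI = round(c(all_v$CI, info_v$CI), 3L),
    RI = round(c(all_v$RI, info_v$RI), 3L))
  structure(c(main, list(variant = variant, both = both)),
            class = "ensemble_indices")
}

#' @export
print.ensemble_indices <- function(x, ...) {
  cat(sprintf("ensemble indices (%s characters): S=%d M=%d G=%d\n",
              x$variant, x$S, x$M, x$G))
  cat(sprintf("  CI = %.3f  RI = %.3f  RC = %.3f\n", x$CI, x$RI, x$RC))
  for (f in x$flags) cat("  note:", f, "\n")
  invisible(x)
}

#' Per-character score table
#'
#' Observed steps, bounds, and per-character consistency/retention indices
#' of a tree; the tabular companion to [ensemble_indices()].
#'
#' @param tree a `phylo`.
#' @param m a [char_matrix()].
#' @return data frame with columns `char`, `name`, `steps`, `min_steps`,
#'   `max_steps`, `ci`, `ri`, `homoplastic`.
#' @export
score_table <- function(tree, m) {
  fl <- fitch_length(tree, m)
  b <- char_bounds(m)
  s <- fl$per_char
  ci <- ifelse(s > 0, b$min_steps / s, NA_real_)
  ri <- ifelse(b$max_steps > b$min_steps,
               (b$max_steps - s) / (b$max_steps - b$min_steps), NA_real_)
  data.frame(char = b$char,
             name = if (!is.null(m$defs)) m$defs$name else NA_character_,
             steps = s, min_steps = b$min_steps, max_steps = b$max_steps,
             ci = round(ci, 3L), ri = round(ri, 3L),
             homoplastic = s > b$min_steps)
}

# ---- ancestral state sets ---------------------------------------------------

# Unit-cost Sankoff down-pass costs for one character on a rooted tree.
# Returns an (n+Nnode) x nstates cost matrix.
.sankoff_down <- function(tree, masks, nstates = MAX_STATES) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  INF <- 1e9
  cost <- matrix(0, nn, nstates)
  for (i in seq_len(n))
    cost[i, ] <- ifelse(bitwAnd(masks[i], bitwShiftL(1L, 0:(nstates - 1L))) > 0L,
                        0, INF)
  edge <- stats::reorder(tree, "postorder")$edge
  for (i in seq_len(nrow(edge))) {
    p <- edge[i, 1L]; c <- edge[i, 2L]
    cost[p, ] <- cost[p, ] + pmin(cost[c, ], min(cost[c, ]) + 1)
  }
  cost
}

# Outside costs u[v, s]: optimal cost of the whole tree minus v's subtree,
# conditional on v having state s (the edge into v is charged here).
.sankoff_up <- function(tree, cost) {
  n <- length(tree$tip.label)
  nn <- nrow(cost); ns <- ncol(cost)
  up <- matrix(0, nn, ns)
  edge <- stats::reorder(tree, "postorder")$edge
  kids <- split(edge[, 2L], edge[, 1L])
  root <- n + 1L
  for (i in rev(seq_len(nrow(edge)))) {  # preorder
    p <- edge[i, 1L]; v <- edge[i, 2L]
    sibs <- setdiff(kids[[as.character(p)]], v)
    base <- up[p, ]
    for (w in sibs) base <- base + pmin(cost[w, ], min(cost[w, ]) + 1)
    # A_p(s) done; charge the p->v edge
    up[v, ] <- pmin(base, min(base) + 1)
  }
  up
}

#' Ancestral state-set reconstruction
#'
#' Preliminary (down-pass) and final (all most-parsimonious
#' reconstructions, MPR) state-sets for every node of a rooted tree under
#' unordered costs, computed by unit-cost dynamic programming, which is
#' exact for polytomies and ambiguous leaves.  On binary trees the
#' preliminary sets equal the classic Fitch down-pass sets and the final
#' sets equal the Fitch up-pass (MPR) sets.
#'
#' @param tree rooted `phylo`.
#' @param m a [char_matrix()].
#' @param char 1-based character index.
#' @return list with `preliminary` and `final`: lists (indexed by ape node
#'   id, tips first) of integer state vectors; plus `steps`, the character's
#'   length on the tree.
#' @export
ancestral_state_sets <- function(tree, m, char) {
  stopifnot(char >= 1L, char <= m$n_char)
  masks <- .tree_states(tree, m)[, char]
  cost <- .sankoff_down(tree, masks)
  up <- .sankoff_up(tree, cost)
  n <- length(tree$tip.label)
  root <- n + 1L
  best <- min(cost[root, ])
  total <- cost + up
  prelim <- lapply(seq_len(nrow(cost)), function(v)
    which(cost[v, ] == min(cost[v, ])) - 1L)
  final <- lapply(seq_len(nrow(cost)), function(v)
    which(total[v, ] == best) - 1L)
  list(preliminary = prelim, final = final, steps = as.integer(best))
}
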