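# Seeded generator of discrete character matrices evolved on known trees,
# emulating the structure morphological parsimony assumes: unordered
# k-state characters (k <= 4) with configurable fractions of missing,
# inapplicable and polymorphic cells, plus a true change log for mapping
# tests.

#' Simulation configuration
#'
#' @param n_taxa number of taxa (>= 3).
#' @param n_char number of characters (>= 1).
#' @param states_per_char states per character, 2..4.
#' @param tree_model `"yule"` (pure-birth) or `"uniform"` (uniform random
#'   topology).
#' @param changes_per_char Poisson mean of state changes per character over
#'   the whole tree.
#' @param missing_frac,inapplicable_frac,polymorphic_frac cell corruption
#'   fractions (must sum to at most 1).
#' @param rate_by_length place changes on branches proportionally to branch
#'   length instead of uniformly (default off; uniform placement keeps the
#'   generator minimal).
#' @param seed integer seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 8L, n_char = 50L, states_per_char = 2L,
                       tree_model = c("yule", "uniform"),
                       changes_per_char = 1,
                       missing_frac = 0, inapplicable_frac = 0,
                       polymorphic_frac = 0, rate_by_length = FALSE,
                       seed = 1L) {
  tree_model <- match.arg(tree_model)
  stopifnot(n_taxa >= 3L, n_char >= 1L,
            states_per_char >= 2L, states_per_char <= 4L,
            changes_per_char >= 0,
            missing_frac >= 0, inapplicable_frac >= 0,
            polymorphic_frac >= 0,
            missing_frac + inapplicable_frac + polymorphic_frac <= 1)
  structure(list(n_taxa = as.integer(n_taxa), n_char = as.integer(n_char),
                 states_per_char = as.integer(states_per_char),
                 tree_model = tree_model,
                 changes_per_char = changes_per_char,
                 missing_frac = missing_frac,
                 inapplicable_frac = inapplicable_frac,
                 polymorphic_frac = polymorphic_frac,
                 rate_by_length = rate_by_length,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a random tree
#'
#' @param cfg a [sim_config()].
#' @return a `phylo` with `n_taxa` leaves labelled `t1..tN`.
#' @export
simulate_tree <- function(cfg) {
  set.seed(cfg$seed)
  tr <- switch(cfg$tree_model,
               yule = ape::rphylo(cfg$n_taxa, birth = 1, death = 0),
               uniform = ape::rtopology(cfg$n_taxa, rooted = TRUE))
  tr$tip.label <- paste0("t", seq_len(cfg$n_taxa))
  tr
}

#' Simulate a character matrix on a tree
#'
#' Each character starts from a uniform root state and accrues a
#' Poisson-distributed number of unordered state changes on uniformly
#' chosen branches (or length-weighted with `rate_by_length`); cells are
#' then corrupted to missing, inapplicable, or polymorphic per the
#' configured fractions.  The true change log is returned so mapping and
#' recovery can be tested against the generating process.
#'
#' @param tree a rooted `phylo` (e.g. from [simulate_tree()]).
#' @param cfg a [sim_config()].
#' @return list with `matrix` (a [char_matrix()]) and `changes` (data frame
#'   `char`, `node` — ape id of the branch's child —, `from`, `to`).
#' @export
simulate_matrix <- function(tree, cfg) {
  set.seed(cfg$seed + 1L)
  n <- length(tree$tip.label)
  edge <- stats::reorder(tree, "cladewise")$edge  # preorder: parents first
  nb_states <- cfg$states_per_char
  probs <- if (cfg$rate_by_length && !is.null(tree$edge.length)) {
    el <- stats::reorder(tree, "cladewise")$edge.length
    el / sum(el)
  } else rep(1 / nrow(edge), nrow(edge))
  sym <- matrix("0", n, cfg$n_char)
  changes <- list()
  for (j in seq_len(cfg$n_char)) {
    state <- integer(n + tree$Nnode)
    state[n + 1L] <- sample.int(nb_states, 1L) - 1L
    k <- rpois(1L, cfg$changes_per_char)
    on_edge <- if (k > 0L) sample.int(nrow(edge), k, replace = TRUE,
                                      prob = probs) else integer(0)
    per_edge <- tabulate(on_edge, nbins = nrow(edge))
    for (i in seq_len(nrow(edge))) {
      p <- edge[i, 1L]; v <- edge[i, 2L]
      s <- state[p]
      for (z in seq_len(per_edge[i])) {
        s_new <- sample(setdiff(0:(nb_states - 1L), s), 1L)
        changes[[length(changes) + 1L]] <-
          data.frame(char = j, node = v, from = s, to = s_new)
        s <- s_new
      }
      state[v] <- s
    }
    sym[, j] <- as.character(state[seq_len(n)])
  }
  # corruption
  u <- matrix(runif(length(sym)), nrow(sym))
  mf <- cfg$missing_frac; inf_ <- cfg$inapplicable_frac
  pf <- cfg$polymorphic_frac
  sym[u < mf] <- "?"
  sym[u >= mf & u < mf + inf_] <- "-"
  poly <- which(u >= mf + inf_ & u < mf + inf_ + pf &
                  grepl("^[0-9]$", sym))
  for (i in poly) {
    s <- as.integer(sym[i])
    other <- sample(setdiff(0:(nb_states - 1L), s), 1L)
    sym[i] <- paste0("{", paste(sort(c(s, other)), collapse = ""), "}")
  }
  rownames(sym) <- tree$tip.label
  mat <- char_matrix(sym, taxa = tree$tip.label,
                     provenance = "simulated")
  list(matrix = mat,
       changes = if (length(changes)) do.call(rbind, changes)
                 else data.frame(char = integer(0), node = integer(0),
                                 from = integer(0), to = integer(0)))
}
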